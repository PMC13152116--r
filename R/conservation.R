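# Alignment-column residue frequencies and property conservation at
# generic (Ballesteros-Weinstein) positions.

.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.canon_aa <- function(x) {
  x <- toupper(x)
  ifelse(nchar(x) == 3 & x %in% names(.aa3to1), .aa3to1[x], x)
}

#' Read an aligned FASTA file
#'
#' @param path Aligned FASTA (protein).
#' @return Character vector of equal-length sequences, named by record.
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty alignment: ", path)
  if (length(unique(Biostrings::width(aa))) != 1L)
    stop("ragged alignment: sequences have unequal lengths")
  stats::setNames(as.character(aa), names(aa))
}

#' Read a column map TSV (`generic_number  column_index  reference_residue`)
#' @param path TSV path.
#' @export
read_column_map <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(generic_number = "character"))
  stopifnot(all(c("generic_number", "column_index") %in% names(m)))
  m
}

#' Residue-count profiles at requested alignment columns
#'
#' @param alignment Character vector of aligned sequences (equal length),
#'   or a path to an aligned FASTA file.
#' @param column_map Data frame with `generic_number` and 1-based
#'   `column_index` (and optionally `reference_residue`).
#' @return Named list (by generic number) of profiles: list with
#'   `position`, `counts` (named integer vector, one-letter codes),
#'   `gaps`, `n_sequences`.  All-gap columns trigger a warning.
#' @export
column_profiles <- function(alignment, column_map) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment))
    alignment <- read_alignment(alignment)
  lens <- unique(nchar(alignment))
  if (length(lens) != 1L) stop("ragged alignment: unequal sequence lengths")
  if (any(column_map$column_index < 1 | column_map$column_index > lens))
    stop("column index out of range (alignment width ", lens, ")")
  n <- length(alignment)
  out <- lapply(seq_len(nrow(column_map)), function(k) {
    col <- toupper(substr(alignment, column_map$column_index[k],
                          column_map$column_index[k]))
    gap <- col %in% c("-", ".", "")
    counts <- table(col[!gap])
    if (all(gap))
      warning("all-gap column at position ", column_map$generic_number[k])
    list(position = column_map$generic_number[k],
         counts = stats::setNames(as.integer(counts), names(counts)),
         gaps = sum(gap), n_sequences = n)
  })
  stats::setNames(out, column_map$generic_number)
}

#' Default residue-to-property class table
#'
#' Follows the cavity analysis's enumerations (Ser/Thr/Cys/Asn small
#' polar; Tyr/Phe/Trp bulky aromatic) extended conventionally over the
#' remaining canonical types.  Classes are disjoint and cover all 20
#' residues.
#' @return Named character vector: one-letter residue -> class.
#' @export
default_property_classes <- function() {
  c(S = "small-polar", T = "small-polar", C = "small-polar",
    N = "small-polar",
    Y = "bulky-aromatic", F = "bulky-aromatic", W = "bulky-aromatic",
    L = "bulky-aliphatic", I = "bulky-aliphatic", M = "bulky-aliphatic",
    V = "bulky-aliphatic",
    R = "charged-positive", K = "charged-positive", H = "charged-positive",
    D = "charged-negative", E = "charged-negative",
    G = "other", A = "other", P = "other", Q = "other")
}

#' Strict-identity class table (each residue is its own class)
#'
#' With this table [property_conservation()] reduces to the reference
#' residue's plain frequency.
#' @export
strict_identity_classes <- function() {
  aa <- unname(.aa3to1)
  stats::setNames(aa, aa)
}

#' Read a property-class TSV (`residue  class`)
#' @param path TSV path (one-letter or three-letter residue codes).
#' @export
read_property_classes <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$class, .canon_aa(tab$residue))
}

#' Property conservation frequency at one position
#'
#' Fraction of non-gap sequences whose residue shares the reference
#' residue's property class.  Gaps are excluded from the denominator; the
#' gap fraction is attached as an attribute.
#'
#' @param profile One element of [column_profiles()].
#' @param reference_type Reference residue (one- or three-letter code).
#' @param classes Residue-to-class table (see
#'   [default_property_classes()]).
#' @return Fraction in `[0, 1]`; `NA` (flagged via attribute `undefined`)
#'   when the column is all gaps.
#' @export
property_conservation <- function(profile, reference_type,
                                  classes = default_property_classes()) {
  ref <- .canon_aa(reference_type)
  if (!ref %in% names(classes))
    stop("reference residue not in class table: ", reference_type)
  tot <- sum(profile$counts)
  if (tot == 0L) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  same <- names(profile$counts)[
    classes[names(profile$counts)] %in% classes[ref] &
      !is.na(classes[names(profile$counts)])]
  out <- sum(profile$counts[same]) / tot
  attr(out, "gap_fraction") <- profile$gaps / profile$n_sequences
  out
}

#' Property-class distribution at a column (the 5.58 dichotomy)
#'
#' @param profile One element of [column_profiles()].
#' @param classes Residue-to-class table.
#' @return Named numeric vector of per-class fractions over non-gap
#'   sequences (sums to 1), with a `gap_fraction` attribute; `NA` flagged
#'   undefined for an all-gap column.
#' @export
class_distribution_558 <- function(profile,
                                   classes = default_property_classes()) {
  tot <- sum(profile$counts)
  if (tot == 0L) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  cls <- classes[names(profile$counts)]
  cls[is.na(cls)] <- "other"
  fr <- tapply(profile$counts, cls, sum) / tot
  out <- stats::setNames(as.numeric(fr), names(fr))
  attr(out, "gap_fraction") <- profile$gaps / profile$n_sequences
  out
}

#' Conservation summary table over mapped positions
#'
#' @param alignment Aligned sequences or FASTA path.
#' @param column_map Data frame with `generic_number`, `column_index`,
#'   `reference_residue`.
#' @param classes Property-class table.
#' @return Data frame: position, reference, reference_frequency,
#'   property_conservation, gap_fraction.
#' @export
conservation_summary <- function(alignment, column_map,
                                 classes = default_property_classes()) {
  stopifnot("reference_residue" %in% names(column_map))
  profs <- column_profiles(alignment, column_map)
  rows <- lapply(seq_along(profs), function(k) {
    p <- profs[[k]]
    ref <- .canon_aa(column_map$reference_residue[k])
    tot <- sum(p$counts)
    data.frame(
      position = p$position, reference = ref,
      reference_frequency = if (tot) sum(p$counts[ref], na.rm = TRUE) / tot
                            else NA_real_,
      property_conservation = as.numeric(
        property_conservation(p, ref, classes)),
      gap_fraction = p$gaps / p$n_sequences,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
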