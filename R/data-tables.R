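# Bundled property tables and the substitution matrix.

.tables_env <- new.env(parent = emptyenv())

read_property_tsv <- function(file) {
  path <- system.file("extdata", file, package = "acetylsite", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(identical(sort(tab$aa), sort(AA20)))
  tab <- tab[match(AA20, tab$aa), , drop = FALSE]
  rownames(tab) <- tab$aa
  tab$aa <- NULL
  tab
}

# One PropertyTable = a named numeric vector over the 20 amino acids plus
# a name attribute; 'X' and the gap symbol carry no value.
property_table <- function(name, values) {
  stopifnot(length(values) == 20L, all(AA20 %in% names(values)))
  structure(list(name = name, values = values[AA20]), class = "property_table")
}

# Look up values for a residue vector; NA for gap/'X'/unknown.
property_lookup <- function(table, residues) {
  unname(table$values[match(residues, AA20)])
}

#' Atchley factor tables
#'
#' The five Atchley factor scores per amino acid (polarity/hydrophobicity,
#' secondary-structure propensity, molecular size, codon composition,
#' electrostatic charge as summarised factors), used for the per-position
#' physicochemical encoding and as the default property set of the
#' auto-cross covariance encoder.
#'
#' @return A list of five `property_table` objects named `Atchley-1` ..
#'   `Atchley-5`.
#' @export
atchley_factors <- function() {
  if (is.null(.tables_env$atchley)) {
    tab <- read_property_tsv("atchley_factors.tsv")
    .tables_env$atchley <- lapply(seq_len(ncol(tab)), function(i) {
      property_table(paste0("Atchley-", i), stats::setNames(tab[[i]], rownames(tab)))
    })
  }
  .tables_env$atchley
}

#' Default physicochemical index set
#'
#' Ten classical amino-acid property scales (Kyte-Doolittle hydropathy,
#' Hopp-Woods hydrophilicity, Grantham polarity and volume, Chou-Fasman
#' helix/sheet/turn propensities, Fauchere-Pliska hydrophobicity,
#' Zimmerman isoelectric point, residue mass) used as the default set of
#' window-averaged property features.
#'
#' @return A list of `property_table` objects, one per scale.
#' @export
aaindex_tables <- function() {
  if (is.null(.tables_env$aaindex)) {
    tab <- read_property_tsv("aaindex_default.tsv")
    .tables_env$aaindex <- lapply(colnames(tab), function(nm) {
      property_table(nm, stats::setNames(tab[[nm]], rownames(tab)))
    })
  }
  .tables_env$aaindex
}

#' Pseudo amino-acid composition property scales
#'
#' The three standard scales (hydrophobicity, hydrophilicity, side-chain
#' mass) used by the parallel-correlation pseudo amino-acid composition
#' encoder, returned un-standardised; the encoder standardises each scale
#' over the 20 residues.
#'
#' @return A list of three `property_table` objects.
#' @export
pseaac_scales <- function() {
  if (is.null(.tables_env$pseaac)) {
    tab <- read_property_tsv("pseaac_scales.tsv")
    .tables_env$pseaac <- lapply(colnames(tab), function(nm) {
      property_table(nm, stats::setNames(tab[[nm]], rownames(tab)))
    })
  }
  .tables_env$pseaac
}

#' BLOSUM62 substitution matrix over the 20 standard amino acids
#'
#' @return A 20 x 20 integer matrix in alphabetical amino-acid order with
#'   attributes `min` and `max` (the extreme scores, used to normalise
#'   fragment similarity into `[0, 1]`).
#' @export
blosum62 <- function() {
  if (is.null(.tables_env$blosum62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    m <- env$BLOSUM62[AA20, AA20]
    storage.mode(m) <- "integer"
    attr(m, "min") <- min(m)
    attr(m, "max") <- max(m)
    .tables_env$blosum62 <- m
  }
  .tables_env$blosum62
}

# 21 x 21 *integer* similarity matrix (codes 1..20 = AA20, 21 = gap or
# unknown): M(a,b) - min(M) for residue pairs, 0 for any gap position.  The
# normalised similarity is this divided by max(M) - min(M); keeping the
# integer form makes distance ties exact, so nearest-neighbour ranking is
# immune to floating-point summation order.
similarity_matrix <- function() {
  if (is.null(.tables_env$simmat)) {
    m <- blosum62()
    out <- matrix(0L, 21L, 21L)
    out[1:20, 1:20] <- m - attr(m, "min")
    attr(out, "range") <- attr(m, "max") - attr(m, "min")
    .tables_env$simmat <- out
  }
  .tables_env$simmat
}
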