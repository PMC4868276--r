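# Parsers for per-residue profile files produced by external predictors.
#
# Supported dialects (one file per protein, any subset may be present):
#   <id>.pssm       PSI-BLAST ASCII matrix: header lines, then one row per
#                   residue with index, residue, 20 integer log-odds and 20
#                   percentage frequencies (divided by 100 and renormalised
#                   into probabilities).
#   <id>.hh         HMM-profile emission table: index, residue, 20
#                   probabilities in alphabetical amino-acid order.
#   <id>.ss2        secondary structure: index, residue, label in {H,E,C},
#                   three probabilities (coil, helix, strand).
#   <id>.struct.tsv per-residue TSV with columns rsa, phi, psi, hseau,
#                   hsead, hsebu, hsebd.
#   <id>.diso       per-residue TSV with column disorder in {0,1}.

#' Parse external-predictor profile files for one protein
#'
#' Scans `dir` for the per-protein profile files described above and
#' assembles a residue profile.  Channels whose file is absent are left
#' `NULL` (missing); every present channel is length-checked against the
#' protein sequence, and probability rows are renormalised to sum to one.
#'
#' @param dir Directory holding the profile files.
#' @param protein A protein record.
#' @return An object of class `"residue_profile"` with elements
#'   `pssm_scores`, `pssm_probs`, `hh_probs`, `ss`, `rsa`, `phi`, `psi`,
#'   `disorder`, `hse` (any of which may be `NULL`).
#' @export
parse_profiles <- function(dir, protein) {
  n <- nchar(protein$sequence)
  prof <- list(protein_id = protein$id, length = n,
               pssm_scores = NULL, pssm_probs = NULL, hh_probs = NULL,
               ss = NULL, rsa = NULL, phi = NULL, psi = NULL,
               disorder = NULL, hse = NULL)
  path <- function(ext) file.path(dir, paste0(protein$id, ext))

  if (file.exists(path(".pssm"))) {
    ps <- parse_pssm(path(".pssm"))
    check_profile_length(nrow(ps$scores), n, path(".pssm"))
    prof$pssm_scores <- ps$scores
    prof$pssm_probs <- ps$probs
  }
  if (file.exists(path(".hh"))) {
    hh <- parse_hh(path(".hh"))
    check_profile_length(nrow(hh), n, path(".hh"))
    prof$hh_probs <- hh
  }
  if (file.exists(path(".ss2"))) {
    ss <- parse_ss2(path(".ss2"))
    check_profile_length(length(ss), n, path(".ss2"))
    prof$ss <- ss
  }
  if (file.exists(path(".struct.tsv"))) {
    st <- parse_struct(path(".struct.tsv"))
    check_profile_length(nrow(st), n, path(".struct.tsv"))
    prof$rsa <- st$rsa
    prof$phi <- st$phi
    prof$psi <- st$psi
    prof$hse <- as.matrix(st[, c("hseau", "hsead", "hsebu", "hsebd")])
    colnames(prof$hse) <- c("hseau", "hsead", "hsebu", "hsebd")
  }
  if (file.exists(path(".diso"))) {
    d <- parse_disorder(path(".diso"))
    check_profile_length(length(d), n, path(".diso"))
    prof$disorder <- d
  }
  structure(prof, class = "residue_profile")
}

#' @export
print.residue_profile <- function(x, ...) {
  chans <- c("pssm_scores", "pssm_probs", "hh_probs", "ss", "rsa", "phi",
             "psi", "disorder", "hse")
  present <- chans[!vapply(x[chans], is.null, logical(1))]
  cat("residue profile ", x$protein_id, " (", x$length, " residues): ",
      if (length(present)) paste(present, collapse = ", ") else "no channels",
      "\n", sep = "")
  invisible(x)
}

check_profile_length <- function(got, expected, file) {
  if (got != expected) {
    stop("profile alignment error: ", basename(file), " has ", got,
         " rows but the sequence has ", expected, " residues")
  }
}

# Renormalise probability rows to sum 1; an all-zero row (possible in
# rounded percentage output) becomes uniform.
renormalize_rows <- function(m, file) {
  if (any(m < 0)) {
    stop("profile format error in ", basename(file), ": negative probability")
  }
  s <- rowSums(m)
  zero <- s <= 0
  m[zero, ] <- 1 / ncol(m)
  m[!zero, ] <- m[!zero, , drop = FALSE] / s[!zero]
  m
}

parse_pssm <- function(file) {
  lines <- readLines(file)
  data_rows <- grep("^\\s*[0-9]+\\s+[A-Za-z]\\s", lines)
  if (length(data_rows) == 0L) {
    stop("profile format error in ", basename(file), ": no matrix rows found")
  }
  scores <- matrix(0, length(data_rows), 20L,
                   dimnames = list(NULL, AA20))
  probs <- scores
  for (i in seq_along(data_rows)) {
    fields <- strsplit(trimws(lines[data_rows[i]]), "\\s+")[[1]]
    if (length(fields) < 42L) {
      stop("profile format error in ", basename(file), " at line ",
           data_rows[i], ": expected 42+ fields, found ", length(fields))
    }
    v <- suppressWarnings(as.numeric(fields[3:42]))
    if (anyNA(v)) {
      stop("profile format error in ", basename(file), " at line ",
           data_rows[i], ": non-numeric matrix entry")
    }
    scores[i, ] <- v[1:20]
    probs[i, ] <- v[21:40] / 100
  }
  list(scores = scores, probs = renormalize_rows(probs, file))
}

parse_hh <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  probs <- matrix(0, length(lines), 20L, dimnames = list(NULL, AA20))
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) < 22L) {
      stop("profile format error in ", basename(file), " at line ", i,
           ": expected 22 fields, found ", length(fields))
    }
    v <- suppressWarnings(as.numeric(fields[3:22]))
    if (anyNA(v)) {
      stop("profile format error in ", basename(file), " at line ", i,
           ": non-numeric probability")
    }
    probs[i, ] <- v
  }
  renormalize_rows(probs, file)
}

parse_ss2 <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  labels <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) < 3L || !(fields[3] %in% c("H", "E", "C"))) {
      stop("profile format error in ", basename(file), " at line ", i,
           ": expected a label in {H,E,C}")
    }
    labels[i] <- fields[3]
  }
  labels
}

parse_struct <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("rsa", "phi", "psi", "hseau", "hsead", "hsebu", "hsebd")
  if (!all(need %in% colnames(tab))) {
    stop("profile format error in ", basename(file), ": missing column(s) ",
         paste(setdiff(need, colnames(tab)), collapse = ", "))
  }
  hse <- as.matrix(tab[, c("hseau", "hsead", "hsebu", "hsebd")])
  if (any(hse < 0)) {
    stop("profile format error in ", basename(file),
         ": negative half-sphere exposure value")
  }
  tab
}

parse_disorder <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!"disorder" %in% colnames(tab)) {
    stop("profile format error in ", basename(file),
         ": missing column 'disorder'")
  }
  if (!all(tab$disorder %in% c(0L, 1L))) {
    stop("profile format error in ", basename(file),
         ": disorder values must be 0 or 1")
  }
  as.logical(tab$disorder)
}
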