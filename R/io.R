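# Sequence / site / feature-matrix input and output.

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased, whitespace inside sequence lines is stripped,
#' and any character outside the 20-letter amino-acid alphabet is mapped to
#' `'X'` with a warning.  Duplicate or empty identifiers are format errors.
#'
#' @param path Path to a FASTA file.
#' @return A named list of protein records; each record is a list with
#'   elements `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !any(nzchar(trimws(lines)))) {
    stop("FASTA format error: file '", path, "' is empty")
  }
  first <- which(nzchar(trimws(lines)))[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("FASTA format error at line ", first, ": expected '>' header")
  }
  headers <- which(startsWith(trimws(lines), ">"))
  proteins <- list()
  n_mapped <- 0L
  for (h in seq_along(headers)) {
    line_no <- headers[h]
    id <- sub("^>\\s*", "", trimws(lines[line_no]))
    id <- strsplit(id, "\\s+")[[1]][1]
    if (is.na(id) || !nzchar(id)) {
      stop("FASTA format error at line ", line_no, ": empty header")
    }
    if (id %in% names(proteins)) {
      stop("FASTA format error at line ", line_no, ": duplicate id '", id, "'")
    }
    to <- if (h < length(headers)) headers[h + 1] - 1L else length(lines)
    body <- if (to >= line_no + 1L) lines[(line_no + 1L):to] else character()
    sq <- toupper(gsub("\\s", "", paste(body, collapse = "")))
    if (!nzchar(sq)) {
      stop("FASTA format error at line ", line_no, ": record '", id,
           "' has no sequence")
    }
    chars <- strsplit(sq, "")[[1]]
    bad <- !(chars %in% c(AA20, "X"))
    if (any(bad)) {
      n_mapped <- n_mapped + sum(bad)
      chars[bad] <- "X"
      sq <- paste(chars, collapse = "")
    }
    proteins[[id]] <- list(id = id, sequence = sq)
  }
  if (n_mapped > 0L) {
    warning(n_mapped, " character(s) outside the amino-acid alphabet mapped to 'X'")
  }
  proteins
}

#' Write protein records to a FASTA file
#'
#' @param proteins Named list of protein records (see [read_fasta()]).
#' @param path Output path.
#' @param width Line width for the sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in proteins) {
    writeLines(paste0(">", p$id), con)
    s <- p$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read lysine-site annotations
#'
#' Reads a tab-separated file with header columns `protein_id`, `position`
#' (1-based) and `label` (`positive`/`negative`/`unknown`, with `1`/`0`/`?`
#' accepted as synonyms).  Every position is validated against the protein
#' sequences; a site whose residue is not `'K'` is rejected unless
#' `permissive = TRUE`.
#'
#' @param path Path to the TSV file.
#' @param proteins Named list of protein records.
#' @param permissive Allow non-lysine centers (default `FALSE`).
#' @return A data frame with columns `protein_id`, `position`, `label`.
#' @export
read_sites <- function(path, proteins, permissive = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "character"))
  need <- c("protein_id", "position", "label")
  if (!all(need %in% colnames(tab))) {
    stop("sites format error: missing column(s) ",
         paste(setdiff(need, colnames(tab)), collapse = ", "))
  }
  syn <- c("1" = "positive", "0" = "negative", "?" = "unknown",
           positive = "positive", negative = "negative", unknown = "unknown")
  lab <- syn[tab$label]
  if (anyNA(lab)) {
    stop("sites format error: unknown label '",
         tab$label[which(is.na(lab))[1]], "'")
  }
  tab$label <- unname(lab)
  validate_sites(tab, proteins, permissive = permissive)
}

# Shared validation for site tables built in memory or read from disk.
validate_sites <- function(sites, proteins, permissive = FALSE) {
  missing_id <- setdiff(sites$protein_id, names(proteins))
  if (length(missing_id) > 0L) {
    stop("site reference error: unknown protein id '", missing_id[1], "'")
  }
  lens <- vapply(proteins, function(p) nchar(p$sequence), integer(1))
  out_of_range <- sites$position < 1L | sites$position > lens[sites$protein_id]
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    stop("site bounds error: position ", sites$position[i],
         " out of range for protein '", sites$protein_id[i], "'")
  }
  res <- substr(vapply(sites$protein_id, function(id) proteins[[id]]$sequence,
                       character(1)),
                sites$position, sites$position)
  if (!permissive && any(res != "K")) {
    i <- which(res != "K")[1]
    stop("non-lysine site: residue '", res[i], "' at ",
         sites$protein_id[i], ":", sites$position[i])
  }
  rownames(sites) <- NULL
  sites[, c("protein_id", "position", "label")]
}

#' Write a site table
#'
#' @param sites Site data frame (`protein_id`, `position`, `label`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites[, c("protein_id", "position", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample negative (non-acetylated) lysine sites
#'
#' Draws non-annotated lysine positions uniformly at random from the
#' proteins that carry positive sites, at `ratio` negatives per positive
#' (the balanced 1:1 design by default).  If fewer candidate lysines exist
#' than requested, all are returned with a warning.
#'
#' @param proteins Named list of protein records.
#' @param positives Data frame of positive sites.
#' @param ratio Negatives per positive (default 1).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A data frame of sites labelled `"negative"`.
#' @export
sample_negatives <- function(proteins, positives, ratio = 1, seed = 1L) {
  stopifnot(ratio > 0)
  pos_key <- paste(positives$protein_id, positives$position)
  cand <- do.call(rbind, lapply(unique(positives$protein_id), function(id) {
    pos <- which(strsplit(proteins[[id]]$sequence, "")[[1]] == "K")
    if (length(pos) == 0L) return(NULL)
    data.frame(protein_id = id, position = pos, stringsAsFactors = FALSE)
  }))
  cand <- cand[!(paste(cand$protein_id, cand$position) %in% pos_key), ,
               drop = FALSE]
  if (is.null(cand) || nrow(cand) == 0L) {
    stop("no candidate lysines available for negative sampling")
  }
  n_want <- round_half_up(ratio * nrow(positives))
  if (nrow(cand) < n_want) {
    warning("only ", nrow(cand), " candidate lysines for ", n_want,
            " requested negatives; using all")
    n_want <- nrow(cand)
  }
  set.seed(seed)
  take <- sort(sample(nrow(cand), n_want))
  out <- cand[take, , drop = FALSE]
  out$label <- "negative"
  rownames(out) <- NULL
  out
}

#' Extract the sliding window around a sequence position
#'
#' Returns the `2L + 1` residues centred on `position`; positions beyond
#' either terminus hold the gap symbol `'-'` and are flagged invalid.  The
#' terminal class is `"N-terminal"` if any upstream position falls outside
#' the sequence, `"C-terminal"` if any downstream position does, and
#' `"middle"` otherwise; a window touching both termini is classed
#' N-terminal.
#'
#' @param protein A protein record.
#' @param position 1-based center position.
#' @param L Window radius; the window length is `2L + 1`.
#' @return An object of class `"seq_window"`.
#' @export
extract_window <- function(protein, position, L = 6L) {
  n <- nchar(protein$sequence)
  stopifnot(position >= 1L, position <= n, L >= 1L)
  idx <- (position - L):(position + L)
  valid <- idx >= 1L & idx <= n
  residues <- rep(GAP, 2L * L + 1L)
  residues[valid] <- strsplit(substr(protein$sequence, max(1L, position - L),
                                     min(n, position + L)), "")[[1]]
  terminal_class <- if (any(!valid[1:L])) "N-terminal"
    else if (any(!valid[(L + 2L):(2L * L + 1L)])) "C-terminal"
    else "middle"
  structure(list(protein_id = protein$id, center_position = position, L = L,
                 residues = residues, valid = valid,
                 terminal_class = terminal_class),
            class = "seq_window")
}

#' @export
print.seq_window <- function(x, ...) {
  cat("sliding window ", x$protein_id, ":", x$center_position,
      " (L = ", x$L, ", ", x$terminal_class, ")\n",
      paste(x$residues, collapse = ""), "\n", sep = "")
  invisible(x)
}

# ---- feature matrix container -----------------------------------------------

#' Construct a feature matrix
#'
#' A numeric sites-by-features matrix carrying the site keys, optional
#' labels, and the subtype tag of every feature (the prefix of its name up
#' to the first dot).
#'
#' @param values Numeric matrix (sites x features) with column names.
#' @param site_keys Data frame with columns `protein_id`, `position`.
#' @param labels Optional character vector aligned with the rows.
#' @return An object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(values, site_keys, labels = NULL) {
  stopifnot(is.matrix(values), !is.null(colnames(values)),
            nrow(values) == nrow(site_keys))
  if (anyDuplicated(colnames(values))) {
    stop("duplicate feature names in feature matrix")
  }
  structure(values,
            site_keys = site_keys[, c("protein_id", "position")],
            labels = labels,
            subtype = sub("\\..*$", "", colnames(values)),
            class = c("feature_matrix", "matrix", "array"))
}

#' Subtype tag of every feature column
#' @param fm A feature matrix.
#' @return Character vector of subtype tags aligned with the columns.
#' @export
feature_subtypes <- function(fm) attr(fm, "subtype")

#' @export
print.feature_matrix <- function(x, ...) {
  tab <- table(attr(x, "subtype"))
  cat("feature matrix: ", nrow(x), " sites x ", ncol(x), " features (",
      length(tab), " subtypes)\n", sep = "")
  print(tab)
  invisible(x)
}

#' Write a feature matrix and its manifest
#'
#' The matrix is written as a TSV (site keys, optional label, then one
#' column per feature at full `%.17g` precision so that a read back is
#' bit-exact) together with a JSON sidecar manifest `<path>.manifest.json`
#' recording feature order and subtype tags.
#'
#' @param fm A feature matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  keys <- attr(fm, "site_keys")
  labels <- attr(fm, "labels")
  head_cols <- c("protein_id", "position", if (!is.null(labels)) "label")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(head_cols, colnames(fm)), collapse = "\t"), con)
  vals <- apply(fm, 1L, function(r) paste(format_full(r), collapse = "\t"))
  lead <- paste(keys$protein_id, keys$position, sep = "\t")
  if (!is.null(labels)) lead <- paste(lead, labels, sep = "\t")
  writeLines(if (nrow(fm) > 0L) paste(lead, vals, sep = "\t") else character(),
             con)
  manifest <- list(features = colnames(fm),
                   subtype = unname(attr(fm, "subtype")),
                   n_sites = nrow(fm))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path (the `.manifest.json` sidecar must sit next to it).
#' @return A feature matrix.
#' @export
read_feature_matrix <- function(path) {
  manifest <- jsonlite::read_json(paste0(path, ".manifest.json"),
                                  simplifyVector = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  has_label <- "label" %in% colnames(tab)[1:3]
  keys <- tab[, c("protein_id", "position")]
  labels <- if (has_label) tab$label else NULL
  vals <- as.matrix(tab[, manifest$features, drop = FALSE])
  feature_matrix(vals, keys, labels)
}
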