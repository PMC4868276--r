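# Synthetic desk-scale datasets: sequences with compositional bias around
# positive sites, labelled lysine sites, and all profile channels with a
# planted depression of the half-sphere-exposure "up" channels at positive
# sites.  Everything is reproducible from the spec seed, and the emitted
# files use exactly the dialects the parsers read.

# Approximate background amino-acid frequencies of the UniProt proteome.
BACKGROUND_AA_FREQ <- c(
  A = 0.0825, C = 0.0137, D = 0.0545, E = 0.0675, F = 0.0386,
  G = 0.0707, H = 0.0227, I = 0.0596, K = 0.0584, L = 0.0966,
  M = 0.0242, N = 0.0406, P = 0.0470, Q = 0.0393, R = 0.0553,
  S = 0.0656, T = 0.0534, V = 0.0687, W = 0.0108, Y = 0.0292)
BACKGROUND_AA_FREQ <- BACKGROUND_AA_FREQ / sum(BACKGROUND_AA_FREQ)

#' Specification of a synthetic acetylation dataset
#'
#' The defaults encode the study conditions the package is exercised
#' under: sequences drawn from proteome-like background frequencies;
#' positive-site flanks enriched in glycine, depleted in glutamate and
#' aspartate, with an extra upstream-lysine boost; and the half-sphere
#' exposure "up" channels depressed at positive-site centers (HSEAU means
#' 8.15 positive vs 9.21 negative, HSEBU 9.72 vs 11.07, shared sd 3.0).
#' Down channels carry no class signal.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Uniform range of sequence lengths.
#' @param positives_per_protein Planted acetylation sites per protein.
#' @param negative_ratio Labelled negatives per positive.
#' @param background Named amino-acid frequency vector.
#' @param enrichment List with `boost` (named log-odds boosts applied on
#'   both flanks), `upstream_boost` (additional upstream-only boosts) and
#'   `radius` (how far from the center the bias extends).
#' @param hse_effect List with `hseau` and `hsebu` class means (named
#'   `positive`/`negative`) and shared `sd`; non-site positions use the
#'   negative means.
#' @param dirichlet_conc Concentration of the profile probability rows on
#'   the true residue (larger = cleaner profiles).
#' @param seed Integer seed; every draw is reproducible from it.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_proteins = 200L,
                           length_range = c(80L, 200L),
                           positives_per_protein = 1L,
                           negative_ratio = 1,
                           background = BACKGROUND_AA_FREQ,
                           enrichment = list(
                             boost = c(G = 0.8, E = -0.8, D = -0.8),
                             upstream_boost = c(K = 0.6),
                             radius = 6L),
                           hse_effect = list(
                             hseau = c(positive = 8.15, negative = 9.21),
                             hsebu = c(positive = 9.72, negative = 11.07),
                             sd = 3.0),
                           dirichlet_conc = 10,
                           seed = 1L) {
  stopifnot(length(length_range) == 2L, length_range[1] <= length_range[2],
            positives_per_protein >= 1L, negative_ratio > 0,
            all(names(background) %in% AA20), abs(sum(background) - 1) < 1e-6,
            hse_effect$sd > 0, all(unlist(hse_effect[c("hseau", "hsebu")]) >= 0))
  structure(list(n_proteins = n_proteins, length_range = length_range,
                 positives_per_protein = positives_per_protein,
                 negative_ratio = negative_ratio, background = background,
                 enrichment = enrichment, hse_effect = hse_effect,
                 dirichlet_conc = dirichlet_conc, seed = seed),
            class = "synthetic_spec")
}

# Dirichlet-like probability row concentrated on the true residue.  The
# rows are quantised exactly as the emitted file dialect stores them
# (`file`), and the in-memory profile keeps the renormalised version
# (`prob`), so parsing the written files reproduces the in-memory values.
draw_profile_rows <- function(residues, conc, digits, scale = 1) {
  n <- length(residues)
  alpha <- matrix(0.2, n, 20L, dimnames = list(NULL, AA20))
  known <- residues %in% AA20
  alpha[cbind(which(known), match(residues[known], AA20))] <- 0.2 + conc
  g <- matrix(stats::rgamma(n * 20L, shape = alpha), n, 20L,
              dimnames = list(NULL, AA20))
  p <- g / rowSums(g)
  q <- round(p * scale, digits) / scale
  s <- rowSums(q)
  prob <- q
  prob[s == 0, ] <- 1 / 20
  prob[s > 0, ] <- q[s > 0, , drop = FALSE] / s[s > 0]
  list(raw = p, file = q, prob = prob)
}

markov_chain <- function(n, states, start_prob, persist) {
  out <- character(n)
  out[1] <- sample(states, 1L, prob = start_prob)
  for (i in seq_len(n - 1L)) {
    out[i + 1L] <- if (stats::runif(1) < persist) out[i]
      else sample(setdiff(states, out[i]), 1L)
  }
  out
}

#' Generate a synthetic acetylation dataset
#'
#' Draws sequences, plants positive lysines with flanking compositional
#' enrichment, labels an equal-ratio sample of the remaining lysines
#' negative, and generates every profile channel (scoring-matrix and
#' HMM-profile probability rows concentrated on the true residue,
#' secondary-structure and disorder run-structure, solvent accessibility,
#' torsions, and half-sphere exposure with the class-dependent up-channel
#' means at site centers).  When `dir` is given the dataset is also written
#' as the file tree the package parsers read (FASTA, sites TSV, per-protein
#' profile files, and a JSON manifest of the spec used); two runs with the
#' same spec produce byte-identical trees.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory.
#' @return A list with `proteins`, `sites`, `profiles` and `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec(), dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  bg <- spec$background[AA20]
  bg[is.na(bg)] <- 0
  names(bg) <- AA20
  rad <- spec$enrichment$radius
  min_len <- 2L * rad + 3L
  if (spec$length_range[1] < min_len) {
    stop("infeasible spec: minimum length ", spec$length_range[1],
         " cannot hold an enrichment window of radius ", rad)
  }

  boost_both <- stats::setNames(rep(0, 20), AA20)
  boost_both[names(spec$enrichment$boost)] <- spec$enrichment$boost
  boost_up <- stats::setNames(rep(0, 20), AA20)
  boost_up[names(spec$enrichment$upstream_boost)] <- spec$enrichment$upstream_boost
  p_flank_down <- bg * exp(boost_both)
  p_flank_up <- bg * exp(boost_both + boost_up)

  proteins <- list()
  positives <- list()
  for (i in seq_len(spec$n_proteins)) {
    id <- sprintf("synP%03d", i)
    len <- sample(spec$length_range[1]:spec$length_range[2], 1L)
    chars <- sample(AA20, len, replace = TRUE, prob = bg)
    cand <- (rad + 1L):(len - rad)
    if (length(cand) < spec$positives_per_protein) {
      stop("infeasible spec: protein of length ", len, " cannot hold ",
           spec$positives_per_protein, " positive sites")
    }
    centers <- sort(sample(cand, spec$positives_per_protein))
    chars[centers] <- "K"
    for (p in centers) {
      for (o in setdiff(-rad:rad, 0L)) {
        pos <- p + o
        if (pos < 1L || pos > len || pos %in% centers) next
        prob <- if (o < 0L) p_flank_up else p_flank_down
        chars[pos] <- sample(AA20, 1L, prob = prob)
      }
    }
    proteins[[id]] <- list(id = id, sequence = paste(chars, collapse = ""))
    positives[[id]] <- data.frame(protein_id = id, position = centers,
                                  label = "positive", stringsAsFactors = FALSE)
  }
  positives <- do.call(rbind, positives)

  # negatives: uniform draw from the remaining lysines
  pos_key <- paste(positives$protein_id, positives$position)
  cand <- do.call(rbind, lapply(proteins, function(p) {
    ks <- which(strsplit(p$sequence, "")[[1]] == "K")
    if (!length(ks)) return(NULL)
    data.frame(protein_id = p$id, position = ks, stringsAsFactors = FALSE)
  }))
  cand <- cand[!(paste(cand$protein_id, cand$position) %in% pos_key), ,
               drop = FALSE]
  n_neg <- min(nrow(cand), round_half_up(spec$negative_ratio * nrow(positives)))
  if (n_neg == 0L) stop("infeasible spec: no candidate negative lysines")
  negatives <- cand[sort(sample(nrow(cand), n_neg)), , drop = FALSE]
  negatives$label <- "negative"
  sites <- rbind(positives, negatives)
  sites <- sites[order(sites$protein_id, sites$position), ]
  rownames(sites) <- NULL

  site_class <- stats::setNames(sites$label,
                                paste(sites$protein_id, sites$position))
  eff <- spec$hse_effect
  profiles <- list()
  for (p in proteins) {
    len <- nchar(p$sequence)
    res <- strsplit(p$sequence, "")[[1]]
    pssm <- draw_profile_rows(res, spec$dirichlet_conc, 0, scale = 100)
    hh <- draw_profile_rows(res, spec$dirichlet_conc, 4)
    scores <- round(2 * log2(pmax(pssm$raw, 1e-4) / rep(bg, each = len)))
    scores <- pmax(pmin(scores, 12), -12)
    ss <- markov_chain(len, c("C", "H", "E"), c(0.45, 0.35, 0.20), 0.85)
    disorder <- markov_chain(len, c("0", "1"), c(0.8, 0.2), 0.9) == "1"
    cls <- site_class[paste(p$id, seq_len(len))]
    mean_au <- ifelse(is.na(cls), eff$hseau[["negative"]], eff$hseau[cls])
    mean_bu <- ifelse(is.na(cls), eff$hsebu[["negative"]], eff$hsebu[cls])
    hse <- cbind(hseau = pmax(0, stats::rnorm(len, mean_au, eff$sd)),
                 hsead = pmax(0, stats::rnorm(len, 20, 3)),
                 hsebu = pmax(0, stats::rnorm(len, mean_bu, eff$sd)),
                 hsebd = pmax(0, stats::rnorm(len, 22, 3)))
    profiles[[p$id]] <- structure(list(
      protein_id = p$id, length = len,
      pssm_scores = pssm_scores_named(scores),
      pssm_probs = pssm$prob,
      pssm_pct = round(pssm$file * 100),
      hh_probs = hh$prob,
      hh_file = hh$file,
      ss = ss,
      rsa = round(stats::runif(len), 3),
      phi = round(pmax(-180, pmin(180, stats::rnorm(len, -65, 25))), 3),
      psi = round(pmax(-180, pmin(180, stats::rnorm(len, 120, 40))), 3),
      disorder = disorder,
      hse = round(hse, 3)), class = "residue_profile")
  }

  out <- list(proteins = proteins, sites = sites, profiles = profiles,
              spec = spec)
  if (!is.null(dir)) write_dataset(out, dir)
  out
}

pssm_scores_named <- function(scores) {
  colnames(scores) <- AA20
  scores
}

# ---- file emission ----------------------------------------------------------

write_profile_files <- function(profile, dir, id) {
  # scoring-matrix dialect: 3 header lines then index, residue, 20 integer
  # log-odds, 20 integer percentage frequencies
  con <- file(file.path(dir, paste0(id, ".pssm")), "w")
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste(" ", paste(c(AA20, AA20), collapse = "   "))), con)
  pct <- profile$pssm_pct %||% round(profile$pssm_probs * 100)
  for (i in seq_len(profile$length)) {
    writeLines(paste(sprintf("%5d", i), "K",
                     paste(sprintf("%3d", profile$pssm_scores[i, ]),
                           collapse = " "),
                     paste(sprintf("%3d", pct[i, ]), collapse = " ")), con)
  }
  close(con)
  con <- file(file.path(dir, paste0(id, ".hh")), "w")
  writeLines("# HMM profile emission probabilities", con)
  hh_file <- profile$hh_file %||% profile$hh_probs
  for (i in seq_len(profile$length)) {
    writeLines(paste(i, "K", paste(sprintf("%.4f", hh_file[i, ]),
                                   collapse = " ")), con)
  }
  close(con)
  con <- file(file.path(dir, paste0(id, ".ss2")), "w")
  writeLines(c("# PSIPRED VFORMAT", ""), con)
  for (i in seq_len(profile$length)) {
    probs <- c(C = 0.1, H = 0.1, E = 0.1)
    probs[profile$ss[i]] <- 0.8
    writeLines(paste(sprintf("%4d", i), "K", profile$ss[i],
                     paste(sprintf("%.3f", probs), collapse = " ")), con)
  }
  close(con)
  st <- data.frame(idx = seq_len(profile$length),
                   rsa = sprintf("%.3f", profile$rsa),
                   phi = sprintf("%.3f", profile$phi),
                   psi = sprintf("%.3f", profile$psi),
                   hseau = sprintf("%.3f", profile$hse[, "hseau"]),
                   hsead = sprintf("%.3f", profile$hse[, "hsead"]),
                   hsebu = sprintf("%.3f", profile$hse[, "hsebu"]),
                   hsebd = sprintf("%.3f", profile$hse[, "hsebd"]))
  utils::write.table(st, file.path(dir, paste0(id, ".struct.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(idx = seq_len(profile$length),
                                disorder = as.integer(profile$disorder)),
                     file.path(dir, paste0(id, ".diso")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prof_dir <- file.path(dir, "profiles")
  dir.create(prof_dir, showWarnings = FALSE)
  write_fasta(dataset$proteins, file.path(dir, "proteins.fasta"))
  write_sites(dataset$sites, file.path(dir, "sites.tsv"))
  for (id in names(dataset$profiles)) {
    write_profile_files(dataset$profiles[[id]], prof_dir, id)
  }
  manifest <- unclass(dataset$spec)
  manifest$background <- as.list(manifest$background)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# ---- worked example ---------------------------------------------------------

WORKED_EXAMPLE_SEQ <- paste0("MSGKAEDLLRQVGEK", "ASDFGHKMLNPQRST", "VWYACDEFGK")

#' Miniature worked-example fixture
#'
#' One 40-residue protein with two positive (positions 4 and 22) and two
#' negative (15 and 40) lysine sites and a complete, deterministic set of
#' profile files, written in the exact dialects the parsers read.  The
#' expected feature matrix for this fixture ships with the package (see
#' [worked_example_golden()]).
#'
#' @param dir Directory to write the fixture files into.
#' @return A list with `proteins`, `sites`, `profiles` and `dir`.
#' @export
make_worked_example <- function(dir = tempfile("worked_example_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  protein <- list(id = "wexP1", sequence = WORKED_EXAMPLE_SEQ)
  sites <- data.frame(protein_id = "wexP1",
                      position = c(4L, 15L, 22L, 40L),
                      label = c("positive", "negative", "positive", "negative"),
                      stringsAsFactors = FALSE)
  set.seed(424242)
  len <- nchar(protein$sequence)
  res <- strsplit(protein$sequence, "")[[1]]
  pssm <- draw_profile_rows(res, 10, 0, scale = 100)
  scores <- round(2 * log2(pmax(pssm$raw, 1e-4) /
                             rep(BACKGROUND_AA_FREQ[AA20], each = len)))
  scores <- pmax(pmin(scores, 12), -12)
  hh <- draw_profile_rows(res, 10, 4)
  profile <- structure(list(
    protein_id = "wexP1", length = len,
    pssm_scores = pssm_scores_named(scores),
    pssm_probs = pssm$prob,
    pssm_pct = round(pssm$file * 100),
    hh_probs = hh$prob,
    hh_file = hh$file,
    ss = markov_chain(len, c("C", "H", "E"), c(0.45, 0.35, 0.20), 0.85),
    rsa = round(stats::runif(len), 3),
    phi = round(pmax(-180, pmin(180, stats::rnorm(len, -65, 25))), 3),
    psi = round(pmax(-180, pmin(180, stats::rnorm(len, 120, 40))), 3),
    disorder = markov_chain(len, c("0", "1"), c(0.8, 0.2), 0.9) == "1",
    hse = round(cbind(hseau = pmax(0, stats::rnorm(len, 9, 3)),
                      hsead = pmax(0, stats::rnorm(len, 20, 3)),
                      hsebu = pmax(0, stats::rnorm(len, 11, 3)),
                      hsebd = pmax(0, stats::rnorm(len, 22, 3))), 3)),
    class = "residue_profile")
  write_fasta(list(protein), file.path(dir, "proteins.fasta"))
  write_sites(sites, file.path(dir, "sites.tsv"))
  write_profile_files(profile, dir, "wexP1")
  list(proteins = stats::setNames(list(protein), "wexP1"), sites = sites,
       profiles = stats::setNames(list(profile), "wexP1"), dir = dir)
}

#' Expected feature matrix of the worked example
#'
#' Reads the frozen feature matrix shipped with the package for the
#' [make_worked_example()] fixture (all subtypes except the two
#' evolutionary scoring-matrix blocks, which are checked by recomputation).
#'
#' @return A feature matrix.
#' @export
worked_example_golden <- function() {
  read_feature_matrix(system.file("extdata", "worked_example_features.tsv",
                                  package = "acetylsite", mustWork = TRUE))
}
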