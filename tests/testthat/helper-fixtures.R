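# Shared fixtures, built in code at test time.

# A window object constructed directly (not via extract_window), so tests
# can use arbitrary residue strings including even lengths and gaps.
toy_window <- function(residues, protein_id = "toy", center = 1L,
                       terminal_class = "middle") {
  res <- strsplit(residues, "")[[1]]
  stopifnot(length(res) %% 2L == 1L || terminal_class == "middle")
  structure(list(protein_id = protein_id, center_position = center,
                 L = (length(res) - 1L) %/% 2L,
                 residues = res, valid = res != "-",
                 terminal_class = terminal_class),
            class = "seq_window")
}

homopolymer_window <- function(aa, L = 6L) {
  toy_window(paste(rep(aa, 2L * L + 1L), collapse = ""))
}

random_window <- function(L = 6L, protein_id = "rnd", center = 1L) {
  toy_window(paste(sample(acetylsite:::AA20, 2L * L + 1L, replace = TRUE),
                   collapse = ""),
             protein_id = protein_id, center = center)
}

# A small deterministic residue profile for a given protein, exercising all
# channels without going through the synthetic generator.
toy_profile <- function(protein, seed = 11L) {
  set.seed(seed)
  n <- nchar(protein$sequence)
  probs <- matrix(stats::rgamma(n * 20L, 0.5), n, 20L)
  probs <- probs / rowSums(probs)
  colnames(probs) <- acetylsite:::AA20
  hh <- matrix(stats::rgamma(n * 20L, 0.5), n, 20L)
  hh <- hh / rowSums(hh)
  colnames(hh) <- acetylsite:::AA20
  scores <- matrix(sample(-6:8, n * 20L, replace = TRUE), n, 20L,
                   dimnames = list(NULL, acetylsite:::AA20))
  structure(list(protein_id = protein$id, length = n,
                 pssm_scores = scores, pssm_probs = probs, hh_probs = hh,
                 ss = sample(c("H", "E", "C"), n, replace = TRUE),
                 rsa = round(stats::runif(n), 3),
                 phi = round(stats::rnorm(n, -65, 20), 3),
                 psi = round(stats::rnorm(n, 120, 30), 3),
                 disorder = stats::runif(n) < 0.3,
                 hse = matrix(round(stats::rgamma(n * 4L, 20, 2), 3), n, 4L,
                              dimnames = list(NULL, c("hseau", "hsead",
                                                      "hsebu", "hsebd")))),
            class = "residue_profile")
}

# Small cached synthetic dataset reused across tests.
small_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(synthetic_spec(n_proteins = 40L, seed = 99L))
    }
    cache
  }
})

# Brute-force nearest-neighbour scores, independent of encode_knn's
# vectorised path: plain loops over knn_distance.
brute_knn <- function(window, windows, labels, fractions, exclude_self) {
  keep <- rep(TRUE, length(windows))
  if (exclude_self) {
    keep <- !vapply(windows, function(w) {
      w$protein_id == window$protein_id &&
        w$center_position == window$center_position
    }, logical(1))
  }
  d <- vapply(windows[keep], function(w) knn_distance(window, w), numeric(1))
  ord <- order(d)
  lab <- labels[keep][ord]
  n <- length(d)
  vapply(fractions, function(f) {
    k <- min(n, max(1L, floor(f * n + 0.5)))
    mean(lab[seq_len(k)] == "positive")
  }, numeric(1))
}
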