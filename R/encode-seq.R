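# Sequence-derived feature encoders.  Every encoder is a pure function of
# the window (plus static tables): invalid (out-of-sequence) positions
# contribute nothing — they are excluded from counts and denominators where
# a count is defined, and encoded as zero where a fixed-length block is
# defined.  Feature names follow `<SUBTYPE>.<detail>` so a feature's
# subtype is always the prefix before the first dot.

#' Terminal-location coding
#'
#' One-hot 3-vector of the window's terminal class: N-terminal (1,0,0),
#' middle (0,1,0), C-terminal (0,0,1).
#'
#' @param window A sliding window from [extract_window()].
#' @return Named numeric vector of length 3.
#' @export
encode_lc <- function(window) {
  out <- stats::setNames(numeric(3), c("LC.Nterm", "LC.middle", "LC.Cterm"))
  out[match(window$terminal_class, c("N-terminal", "middle", "C-terminal"))] <- 1
  out
}

#' Position-weight amino-acid composition
#'
#' For each amino acid `i`,
#' `C_i = 1/(L(L+1)) * sum_{j=-L..L} x_{i,j} (j + |j|/L)`, where `x_{i,j}`
#' is 1 when the residue at window offset `j` is amino acid `i`.  The sum
#' runs over the whole window including the center (whose weight is zero);
#' invalid positions contribute nothing.
#'
#' @param window A sliding window.
#' @return Named numeric vector of length 20.
#' @export
encode_pwaa <- function(window) {
  L <- window$L
  j <- -L:L
  w <- (j + abs(j) / L) / (L * (L + 1))
  out <- stats::setNames(numeric(20), paste0("PWAA.", AA20))
  ok <- window$valid & window$residues %in% AA20
  for (k in which(ok)) {
    aa <- window$residues[k]
    out[paste0("PWAA.", aa)] <- out[paste0("PWAA.", aa)] + w[k]
  }
  out
}

# Residue group membership for the grouped-weight encoding:
# C1 hydrophobic, C2 polar, C3 positively charged, C4 negatively charged.
EBGW_C1 <- c("A", "F", "G", "I", "L", "M", "P", "V", "W")
EBGW_C2 <- c("C", "N", "Q", "S", "T", "Y")
EBGW_C3 <- c("H", "K", "R")
EBGW_C4 <- c("D", "E")

#' Encoding based on grouped weight
#'
#' Projects the window onto three binary sequences from hydropathy/charge
#' group unions (H1: hydrophobic+polar, H2: hydrophobic+positive, H3:
#' hydrophobic+negative), then summarises each by `K` growing prefixes:
#' `X(k) = sum(k) / Int(N k / K)` where `Int` rounds half up and `sum(k)`
#' counts ones in the first `Int(N k / K)` window positions.  Invalid
#' positions are zero in all three binary sequences.
#'
#' @param window A sliding window.
#' @param K Number of prefix statistics per binary sequence (default 5).
#' @return Named numeric vector of length `3 K`.
#' @export
encode_ebgw <- function(window, K = 5L) {
  stopifnot(K >= 1L)
  res <- window$residues
  ok <- window$valid
  h <- rbind(H1 = ok & res %in% c(EBGW_C1, EBGW_C2),
             H2 = ok & res %in% c(EBGW_C1, EBGW_C3),
             H3 = ok & res %in% c(EBGW_C1, EBGW_C4))
  N <- length(res)
  lens <- round_half_up(N * seq_len(K) / K)
  out <- numeric(0)
  for (g in rownames(h)) {
    x <- vapply(lens, function(l) sum(h[g, seq_len(l)]) / l, numeric(1))
    out <- c(out, stats::setNames(x, paste0("EBGW.", g, ".k", seq_len(K))))
  }
  out
}

#' Composition of k-spaced amino-acid pairs
#'
#' For every ordered pair `(a, b)` of the 20 amino acids, the fraction
#' `N_ab / N_Total` of window pairs whose members sit `k` positions apart
#' (adjacent for `k = 0`) and are both valid.  The 400 components sum to 1
#' whenever at least one valid pair exists, and are all zero otherwise.
#'
#' @param window A sliding window.
#' @param k Spacing between pair members (default 0).
#' @return Named numeric vector of length 400.
#' @export
encode_cksaap <- function(window, k = 0L) {
  stopifnot(k >= 0L)
  n <- length(window$residues)
  if (n < k + 2L) stop("window too short for any ", k, "-spaced pair")
  names <- paste0("CKSAAP.", rep(AA20, each = 20L), AA20)
  out <- stats::setNames(numeric(400), names)
  i <- seq_len(n - k - 1L)
  a <- window$residues[i]
  b <- window$residues[i + k + 1L]
  usable <- window$valid[i] & window$valid[i + k + 1L] &
    a %in% AA20 & b %in% AA20
  if (!any(usable)) return(out)
  counts <- table(paste0("CKSAAP.", a[usable], b[usable]))
  out[names(counts)] <- as.numeric(counts)
  out / sum(usable)
}

#' Normalised BLOSUM62 distance between two sliding windows
#'
#' `D(S1, S2) = 1 - sum_i sim(S1(i), S2(i)) / (2L + 1)` with
#' `sim(a, b) = (M(a, b) - min(M)) / (max(M) - min(M))` under BLOSUM62.
#' Positions where either window is invalid (or the residue unknown)
#' contribute similarity 0, i.e. maximal dissimilarity.
#'
#' @param s1,s2 Sliding windows of equal radius.
#' @return A distance in `[0, 1]`.
#' @export
knn_distance <- function(s1, s2) {
  if (s1$L != s2$L) stop("window radius mismatch: ", s1$L, " vs ", s2$L)
  sim <- similarity_matrix()
  a <- aa_code(ifelse(s1$valid, s1$residues, GAP))
  b <- aa_code(ifelse(s2$valid, s2$residues, GAP))
  # integer similarity total, one exact division: ties are exact
  1 - sum(sim[cbind(a, b)]) / (attr(sim, "range") * (2 * s1$L + 1))
}

#' Build a nearest-neighbour reference set
#'
#' Packs labelled windows into the integer-coded form used by
#' [encode_knn()].  All windows must share one radius.
#'
#' @param windows List of sliding windows.
#' @param labels Character vector (`"positive"`/`"negative"`) aligned with
#'   `windows`.
#' @param fractions Neighbourhood sizes as fractions of the reference size
#'   (default 1/2, 1/4, 1/8, 1/16, 1/32); must be strictly decreasing.
#' @return An object of class `"knn_reference"`.
#' @export
knn_reference <- function(windows, labels,
                          fractions = c(1/2, 1/4, 1/8, 1/16, 1/32)) {
  stopifnot(length(windows) == length(labels), length(windows) > 0L,
            all(labels %in% c("positive", "negative")),
            all(diff(fractions) < 0), all(fractions > 0), all(fractions <= 1))
  Ls <- vapply(windows, function(w) w$L, integer(1))
  if (length(unique(Ls)) != 1L) stop("reference windows must share one radius")
  codes <- t(vapply(windows,
                    function(w) aa_code(ifelse(w$valid, w$residues, GAP)),
                    integer(2L * Ls[1] + 1L)))
  keys <- vapply(windows, function(w)
    paste(w$protein_id, w$center_position), character(1))
  structure(list(codes = codes, labels = labels, keys = keys,
                 L = Ls[1], fractions = fractions),
            class = "knn_reference")
}

#' Nearest-neighbour scores of a window against a labelled reference
#'
#' For each neighbourhood fraction `f`, the proportion of positive labels
#' among the `K = max(1, round(f * n))` reference fragments closest to the
#' query under the BLOSUM62 window distance (`n` = reference fragments
#' available to the query).  Ties in distance are broken by reference
#' insertion order.  With `exclude_self = TRUE` a reference fragment with
#' the query's own (protein, position) key is omitted — the leave-one-out
#' convention used when encoding training sites.
#'
#' @param window A sliding window.
#' @param ref A [knn_reference()].
#' @param exclude_self Drop the query itself from the reference.
#' @return Named numeric vector, one score in `[0, 1]` per fraction.
#' @export
encode_knn <- function(window, ref, exclude_self = TRUE) {
  if (window$L != ref$L) stop("window radius mismatch with reference")
  keep <- rep(TRUE, nrow(ref$codes))
  if (exclude_self) {
    keep <- ref$keys != paste(window$protein_id, window$center_position)
  }
  if (!any(keep)) stop("reference empty after self-exclusion")
  sim <- similarity_matrix()
  q <- aa_code(ifelse(window$valid, window$residues, GAP))
  width <- 2L * ref$L + 1L
  simsum <- integer(sum(keep))
  codes <- ref$codes[keep, , drop = FALSE]
  for (j in seq_len(width)) {
    simsum <- simsum + sim[codes[, j], q[j]]
  }
  # distance is a decreasing function of the integer similarity total, so
  # ranking on -simsum is exact; ties keep reference insertion order
  ord <- order(-simsum)
  pos <- ref$labels[keep][ord] == "positive"
  n <- length(simsum)
  ks <- pmin(n, pmax(1L, round_half_up(ref$fractions * n)))
  out <- vapply(ks, function(k) mean(pos[seq_len(k)]), numeric(1))
  stats::setNames(out, paste0("KNN.f", seq_along(ref$fractions)))
}

#' Auto-cross covariance over window property profiles
#'
#' Maps the window's valid residues to numeric profiles under each property
#' table, then computes, for each lag `g` in `1..max_lag`, the auto
#' covariance `AC(u, g) = 1/(N_v - g) * sum_i (P_u(i) - mean_u)(P_u(i+g) -
#' mean_u)` for every property `u` and the cross covariance `CC(u, v, g)`
#' for every ordered pair `u != v`, over the compacted sequence of the
#' `N_v` valid positions.  Residues without a property value (`X`) are
#' excluded along with invalid positions.
#'
#' @param window A sliding window.
#' @param properties List of property tables (default: the five Atchley
#'   factors).
#' @param max_lag Maximum lag (default 2).
#' @return Named numeric vector of length `max_lag * p^2` for `p`
#'   properties.
#' @export
encode_acc <- function(window, properties = atchley_factors(), max_lag = 2L) {
  ok <- window$valid & window$residues %in% AA20
  res <- window$residues[ok]
  nv <- length(res)
  if (nv < max_lag + 1L) {
    stop("auto-cross covariance needs more than max_lag valid positions (",
         nv, " available)")
  }
  p <- length(properties)
  prof <- vapply(properties, function(tb) property_lookup(tb, res), numeric(nv))
  cent <- sweep(prof, 2L, colMeans(prof))
  nms <- vapply(properties, function(tb) tb$name, character(1))
  out <- numeric(0)
  for (g in seq_len(max_lag)) {
    i <- seq_len(nv - g)
    cov_g <- crossprod(cent[i, , drop = FALSE],
                       cent[i + g, , drop = FALSE]) / (nv - g)
    vals <- as.vector(t(cov_g))       # row-major: u fixed, v running
    names(vals) <- paste0("ACC.g", g, ".", rep(nms, each = p), ".", nms)
    out <- c(out, vals)
  }
  out
}

#' Parallel-correlation pseudo amino-acid composition
#'
#' Chou-type composition of the window's valid residues: 20 composition
#' components plus `lambda` sequence-order correlation factors built from
#' the hydrophobicity, hydrophilicity and side-chain mass scales (each
#' standardised over the 20 residues using the population SD), combined
#' with weight `w` so that all `20 + lambda` components sum to 1.
#'
#' @param window A sliding window.
#' @param lambda Number of correlation tiers (default 2); must be smaller
#'   than the number of valid residues.
#' @param weight Weight of the sequence-order terms (default 0.05).
#' @return Named numeric vector of length `20 + lambda`.
#' @export
encode_pc_pseaac <- function(window, lambda = 2L, weight = 0.05) {
  ok <- window$valid & window$residues %in% AA20
  res <- window$residues[ok]
  nv <- length(res)
  if (lambda >= nv) {
    stop("pseudo amino-acid composition needs lambda < valid length (",
         nv, " valid residues)")
  }
  scales <- lapply(pseaac_scales(), function(tb) {
    v <- tb$values
    (v - mean(v)) / sqrt(sum((v - mean(v))^2) / 20)
  })
  prof <- vapply(scales, function(s) unname(s[res]), numeric(nv))
  theta <- numeric(lambda)
  if (lambda > 0L) {
    for (g in seq_len(lambda)) {
      i <- seq_len(nv - g)
      theta[g] <- mean(rowMeans((prof[i, , drop = FALSE] -
                                   prof[i + g, , drop = FALSE])^2))
    }
  }
  f <- tabulate(match(res, AA20), nbins = 20L) / nv
  denom <- sum(f) + weight * sum(theta)
  out <- c(f / denom, weight * theta / denom)
  names(out) <- c(paste0("PCPse.comp.", AA20),
                  if (lambda > 0L) paste0("PCPse.lambda", seq_len(lambda)))
  out
}

#' Physicochemical property encoding
#'
#' Two blocks: (i) for each *averaged* property table, the mean of the
#' property over the window's valid residues (residues without a value are
#' excluded from the denominator); (ii) for each *per-position* table
#' (default: the five Atchley factors), the property value at every window
#' position, zero at invalid positions — `5 (2L + 1)` features under the
#' defaults.
#'
#' @param window A sliding window.
#' @param averaged List of property tables averaged over the window
#'   (default: [aaindex_tables()]).
#' @param per_position List of property tables encoded per position
#'   (default: [atchley_factors()]).
#' @return Named numeric vector.
#' @export
encode_aaindex <- function(window, averaged = aaindex_tables(),
                           per_position = atchley_factors()) {
  ok <- window$valid & window$residues %in% AA20
  res_ok <- window$residues[ok]
  out <- numeric(0)
  for (tb in averaged) {
    v <- if (length(res_ok)) mean(property_lookup(tb, res_ok)) else 0
    out <- c(out, stats::setNames(v, paste0("AAindex.avg.", tb$name)))
  }
  offs <- offset_tags(window$L)
  for (tb in per_position) {
    v <- numeric(length(window$residues))
    v[ok] <- property_lookup(tb, res_ok)
    out <- c(out, stats::setNames(v, paste0("AAindex.", tb$name, ".", offs)))
  }
  out
}

# Window offset tags j-6 ... j0 ... j+6 used in per-position feature names.
offset_tags <- function(L) {
  j <- -L:L
  paste0("j", ifelse(j > 0, paste0("+", j), j))
}
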