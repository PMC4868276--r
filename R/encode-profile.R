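# Encoders over external-predictor channels.  Each consumes a window
# profile (the residue-profile rows for the 2L+1 window positions); a
# channel that was never parsed raises a "channel missing" error rather
# than silently emitting zeros.  Positions outside the sequence are encoded
# as zeros.  Concatenation order is always upstream-to-downstream.

#' Slice a residue profile to the positions of a sliding window
#'
#' @param profile A residue profile from [parse_profiles()].
#' @param window A sliding window on the same protein.
#' @return An object of class `"window_profile"`: the profile rows for the
#'   `2L + 1` window positions with invalid positions flagged.
#' @export
window_profile <- function(profile, window) {
  if (!is.null(profile$protein_id) &&
      !identical(profile$protein_id, window$protein_id)) {
    stop("profile/window protein mismatch: ", profile$protein_id, " vs ",
         window$protein_id)
  }
  idx <- (window$center_position - window$L):(window$center_position + window$L)
  valid <- window$valid
  pick_rows <- function(m) {
    if (is.null(m)) return(NULL)
    out <- matrix(0, length(idx), ncol(m), dimnames = list(NULL, colnames(m)))
    out[valid, ] <- m[idx[valid], , drop = FALSE]
    out
  }
  pick_vec <- function(v, fill) {
    if (is.null(v)) return(NULL)
    out <- rep(fill, length(idx))
    out[valid] <- v[idx[valid]]
    out
  }
  structure(list(L = window$L, valid = valid,
                 pssm_scores = pick_rows(profile$pssm_scores),
                 pssm_probs = pick_rows(profile$pssm_probs),
                 hh_probs = pick_rows(profile$hh_probs),
                 ss = pick_vec(profile$ss, NA_character_),
                 rsa = pick_vec(profile$rsa, 0),
                 phi = pick_vec(profile$phi, 0),
                 psi = pick_vec(profile$psi, 0),
                 disorder = pick_vec(profile$disorder, FALSE),
                 hse = pick_rows(profile$hse)),
            class = "window_profile")
}

channel_or_stop <- function(wp, channel) {
  v <- wp[[channel]]
  if (is.null(v)) {
    stop("channel missing: '", channel, "' was not parsed for this protein")
  }
  v
}

#' Secondary-structure encoding
#'
#' Per window position, a one-hot 3-vector of the predicted state:
#' H (1,0,0), C (0,1,0), E (0,0,1); invalid positions are (0,0,0).
#'
#' @param wp A window profile.
#' @return Named numeric vector of length `3 (2L + 1)`.
#' @export
encode_ss <- function(wp) {
  ss <- channel_or_stop(wp, "ss")
  offs <- offset_tags(wp$L)
  out <- numeric(0)
  for (k in seq_along(ss)) {
    v <- stats::setNames(numeric(3), paste0("SS.", c("H", "C", "E"), ".", offs[k]))
    if (wp$valid[k] && !is.na(ss[k])) {
      v[paste0("SS.", ss[k], ".", offs[k])] <- 1
    }
    out <- c(out, v)
  }
  out
}

#' Solvent-accessibility and backbone-torsion encoding
#'
#' Per window position the triple (RSA, psi, phi), angles in degrees passed
#' through unchanged; invalid positions contribute zeros.
#'
#' @param wp A window profile.
#' @return Named numeric vector of length `3 (2L + 1)`.
#' @export
encode_rsa_torsion <- function(wp) {
  rsa <- channel_or_stop(wp, "rsa")
  psi <- channel_or_stop(wp, "psi")
  phi <- channel_or_stop(wp, "phi")
  offs <- offset_tags(wp$L)
  out <- numeric(0)
  for (k in seq_along(rsa)) {
    out <- c(out, stats::setNames(c(rsa[k], psi[k], phi[k]),
                                  paste0("RSA.", c("rsa", "psi", "phi"), ".",
                                         offs[k])))
  }
  out
}

#' Disorder encoding
#'
#' Per window position, 1 for a disordered residue and 0 for an ordered
#' one; invalid positions are 0.
#'
#' @param wp A window profile.
#' @return Named numeric vector of length `2L + 1`.
#' @export
encode_disorder <- function(wp) {
  d <- channel_or_stop(wp, "disorder")
  stats::setNames(as.numeric(d), paste0("Disorder.", offset_tags(wp$L)))
}

#' Half-sphere exposure encoding
#'
#' Per window position the 4-tuple (HSEAU, HSEAD, HSEBU, HSEBD) — the
#' counts of neighbouring C-alpha atoms in the upper/lower half-spheres
#' under the two definitional variants; invalid positions contribute zeros.
#'
#' @param wp A window profile.
#' @return Named numeric vector of length `4 (2L + 1)`.
#' @export
encode_hse <- function(wp) {
  hse <- channel_or_stop(wp, "hse")
  offs <- offset_tags(wp$L)
  chans <- c("hseau", "hsead", "hsebu", "hsebd")
  out <- numeric(0)
  for (k in seq_len(nrow(hse))) {
    out <- c(out, stats::setNames(hse[k, ], paste0("HSE.", chans, ".", offs[k])))
  }
  out
}

#' Entropy conservation score
#'
#' Shannon entropy in bits of each 20-way occurrence-probability vector,
#' `ECS(i) = -sum_j p_{i,j} log2(p_{i,j})` with `0 log 0 = 0`; ranges from
#' 0 (fully conserved) to `log2(20)` (uniform).
#'
#' @param probs Numeric matrix with 20 columns, one probability vector per
#'   row (each summing to 1), or a single vector of length 20.
#' @return Numeric vector of entropies, one per row.
#' @export
compute_ecs <- function(probs) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1L)
  stopifnot(ncol(probs) == 20L)
  if (any(probs < 0)) stop("negative probability in conservation score input")
  plogp <- probs * log2(probs)
  plogp[probs == 0] <- 0
  -rowSums(plogp)
}

#' Evolutionary scoring-matrix encoding (sequence-profile search)
#'
#' Per window position: the 20 log-odds conservation scores, the 20
#' occurrence probabilities, and the entropy conservation score of the
#' probabilities — 41 values per position, zeros at invalid positions.
#'
#' @param wp A window profile.
#' @return Named numeric vector of length `41 (2L + 1)`.
#' @export
encode_pssm <- function(wp) {
  scores <- channel_or_stop(wp, "pssm_scores")
  probs <- channel_or_stop(wp, "pssm_probs")
  offs <- offset_tags(wp$L)
  ecs <- compute_ecs(probs)
  ecs[!wp$valid] <- 0
  out <- numeric(0)
  for (k in seq_len(nrow(probs))) {
    out <- c(out,
             stats::setNames(scores[k, ], paste0("PSSM.score.", AA20, ".", offs[k])),
             stats::setNames(probs[k, ], paste0("PSSM.prob.", AA20, ".", offs[k])),
             stats::setNames(ecs[k], paste0("PSSM.ecs.", offs[k])))
  }
  out
}

#' HMM-profile encoding
#'
#' Per window position: the 20 profile emission probabilities and their
#' entropy conservation score — 21 values per position, zeros at invalid
#' positions.
#'
#' @param wp A window profile.
#' @return Named numeric vector of length `21 (2L + 1)`.
#' @export
encode_hh <- function(wp) {
  probs <- channel_or_stop(wp, "hh_probs")
  offs <- offset_tags(wp$L)
  ecs <- compute_ecs(probs)
  ecs[!wp$valid] <- 0
  out <- numeric(0)
  for (k in seq_len(nrow(probs))) {
    out <- c(out,
             stats::setNames(probs[k, ], paste0("HH.prob.", AA20, ".", offs[k])),
             stats::setNames(ecs[k], paste0("HH.ecs.", offs[k])))
  }
  out
}
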