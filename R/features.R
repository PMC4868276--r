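# Assembly of the full feature matrix over a set of sites.

# Fixed subtype order used everywhere (matrix assembly, final selected set).
# "PCPse" tags the parallel-correlation pseudo amino-acid composition.
SUBTYPES <- c("LC", "PWAA", "EBGW", "CKSAAP", "KNN", "ACC", "PCPse",
              "AAindex", "SS", "RSA", "Disorder", "HSE", "PSSM", "HH")

SEQ_SUBTYPES <- c("LC", "PWAA", "EBGW", "CKSAAP", "KNN", "ACC", "PCPse",
                  "AAindex")
PROFILE_SUBTYPES <- c("SS", "RSA", "Disorder", "HSE", "PSSM", "HH")

#' Encode a feature matrix for a set of lysine sites
#'
#' Extracts the sliding window of every site and concatenates the selected
#' subtype encoders in the fixed subtype order.  Profile subtypes (SS, RSA,
#' Disorder, HSE, PSSM, HH) require parsed residue profiles; requesting one
#' whose channel is absent raises a channel-missing error.
#'
#' @param proteins Named list of protein records.
#' @param sites Site data frame (`protein_id`, `position`, optional
#'   `label`).
#' @param profiles Optional named list (by protein id) of residue profiles.
#' @param L Window radius (default 6, i.e. window length 13).
#' @param subtypes Subtype tags to encode; defaults to the sequence
#'   subtypes, plus all profile subtypes when `profiles` is given.
#' @param knn_ref Optional [knn_reference()].  When `NULL` and KNN is
#'   requested, the reference is built from the labelled sites themselves
#'   and queries exclude themselves (leave-one-out); pass a training
#'   reference (and `knn_exclude_self = FALSE`) when encoding new sites.
#' @param knn_exclude_self Leave-one-out flag forwarded to [encode_knn()].
#' @param ebgw_K,cksaap_k,acc_max_lag,pseaac_lambda,pseaac_weight Encoder
#'   parameters (see the individual encoders).
#' @return A [feature_matrix()] carrying site keys, labels (when present)
#'   and subtype tags.
#' @export
encode_features <- function(proteins, sites, profiles = NULL, L = 6L,
                            subtypes = NULL, knn_ref = NULL,
                            knn_exclude_self = is.null(knn_ref),
                            ebgw_K = 5L, cksaap_k = 0L, acc_max_lag = 2L,
                            pseaac_lambda = 2L, pseaac_weight = 0.05) {
  if (is.null(subtypes)) {
    subtypes <- if (is.null(profiles)) SEQ_SUBTYPES else SUBTYPES
  }
  unknown <- setdiff(subtypes, SUBTYPES)
  if (length(unknown) > 0L) {
    stop("unknown subtype(s): ", paste(unknown, collapse = ", "))
  }
  subtypes <- SUBTYPES[SUBTYPES %in% subtypes]
  if (any(subtypes %in% PROFILE_SUBTYPES) && is.null(profiles)) {
    stop("channel missing: profile subtypes requested but no profiles given")
  }
  windows <- lapply(seq_len(nrow(sites)), function(i) {
    extract_window(proteins[[sites$protein_id[i]]], sites$position[i], L)
  })
  if ("KNN" %in% subtypes && is.null(knn_ref)) {
    if (is.null(sites$label) || !all(sites$label %in% c("positive", "negative"))) {
      stop("building a nearest-neighbour reference requires labelled sites")
    }
    knn_ref <- knn_reference(windows, sites$label)
  }
  encode_row <- function(i) {
    w <- windows[[i]]
    wp <- NULL
    if (any(subtypes %in% PROFILE_SUBTYPES)) {
      prof <- profiles[[w$protein_id]]
      if (is.null(prof)) {
        stop("channel missing: no profiles parsed for protein '",
             w$protein_id, "'")
      }
      wp <- window_profile(prof, w)
    }
    parts <- lapply(subtypes, function(st) {
      switch(st,
             LC = encode_lc(w),
             PWAA = encode_pwaa(w),
             EBGW = encode_ebgw(w, K = ebgw_K),
             CKSAAP = encode_cksaap(w, k = cksaap_k),
             KNN = encode_knn(w, knn_ref, exclude_self = knn_exclude_self),
             ACC = encode_acc(w, max_lag = acc_max_lag),
             PCPse = encode_pc_pseaac(w, lambda = pseaac_lambda,
                                      weight = pseaac_weight),
             AAindex = encode_aaindex(w),
             SS = encode_ss(wp),
             RSA = encode_rsa_torsion(wp),
             Disorder = encode_disorder(wp),
             HSE = encode_hse(wp),
             PSSM = encode_pssm(wp),
             HH = encode_hh(wp))
    })
    unlist(parts)
  }
  first <- encode_row(1L)
  values <- matrix(0, nrow(sites), length(first),
                   dimnames = list(NULL, names(first)))
  values[1L, ] <- first
  if (nrow(sites) > 1L) {
    for (i in 2:nrow(sites)) values[i, ] <- encode_row(i)
  }
  fm <- feature_matrix(values, sites, labels = sites$label)
  attr(fm, "L") <- L
  attr(fm, "knn_ref") <- knn_ref
  fm
}
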