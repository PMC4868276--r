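# Sequence-derived encoders against closed forms and brute-force oracles.

test_that("terminal-location coding is one-hot in class order", {
  expect_equal(unname(encode_lc(toy_window("AAA", terminal_class = "N-terminal"))),
               c(1, 0, 0))
  expect_equal(unname(encode_lc(toy_window("AAA", terminal_class = "middle"))),
               c(0, 1, 0))
  expect_equal(unname(encode_lc(toy_window("AAA", terminal_class = "C-terminal"))),
               c(0, 0, 1))
})

test_that("position-weight composition matches its closed forms", {
  L <- 6L
  w <- homopolymer_window("K", L)
  pw <- encode_pwaa(w)
  # sum of weights over the full window telescopes to (L+1)/(L(L+1)) = 1/L
  expect_equal(unname(pw["PWAA.K"]), 1 / L)
  expect_true(all(pw[setdiff(names(pw), "PWAA.K")] == 0))

  # single occurrence at offset j = -L contributes (-L + 1)/(L(L+1))
  res <- rep("A", 2 * L + 1)
  res[1] <- "W"
  w2 <- toy_window(paste(res, collapse = ""))
  expect_equal(unname(encode_pwaa(w2)["PWAA.W"]), (-L + 1) / (L * (L + 1)))

  # masked positions contribute nothing
  res[1] <- "-"
  expect_equal(unname(encode_pwaa(toy_window(paste(res, collapse = "")))["PWAA.W"]),
               0)

  # sharp bound: a residue filling the whole downstream flank attains
  # sum_{j=1..L} (j + j/L) / (L(L+1)) = (L+1)/(2L), the maximum possible
  set.seed(21)
  for (i in 1:20) {
    expect_true(all(abs(encode_pwaa(random_window(L))) <=
                      (L + 1) / (2 * L) + 1e-12))
  }
  down <- toy_window(paste(c(rep("A", L + 1), rep("W", L)), collapse = ""))
  expect_equal(unname(encode_pwaa(down)["PWAA.W"]), (L + 1) / (2 * L))

  # the features sum to the total weight of the valid positions
  w3 <- random_window(L)
  jw <- ((-L:L) + abs(-L:L) / L) / (L * (L + 1))
  expect_equal(sum(encode_pwaa(w3)), sum(jw[w3$valid]))
})

test_that("grouped-weight encoding uses round-half-up prefix lengths", {
  # all-hydrophobic window: every bit set in all three projections
  expect_equal(unname(encode_ebgw(homopolymer_window("A"))), rep(1, 15))
  # D is negatively charged: H1 = H2 = 0 but H3 = 1 everywhere
  ebd <- encode_ebgw(homopolymer_window("D"))
  expect_equal(unname(ebd), rep(c(0, 0, 1), each = 5))

  # N = 13, K = 5 prefix lengths are Int(13k/5) = 3, 5, 8, 10, 13:
  # a window with exactly the first three positions hydrophobic exposes the
  # denominators directly
  res <- c(rep("A", 3), rep("D", 10))
  eb <- encode_ebgw(toy_window(paste(res, collapse = "")))
  expect_equal(unname(eb[paste0("EBGW.H1.k", 1:5)]),
               3 / c(3, 5, 8, 10, 13))

  # prefix counts are monotone: sum(k) <= sum(k+1) for random windows
  set.seed(8)
  for (i in 1:20) {
    eb <- encode_ebgw(random_window())
    lens <- acetylsite:::round_half_up(13 * (1:5) / 5)
    for (g in c("H1", "H2", "H3")) {
      sums <- eb[paste0("EBGW.", g, ".k", 1:5)] * lens
      expect_true(all(diff(sums) >= -1e-9))
      expect_true(all(eb >= 0 & eb <= 1))
    }
  }
})

test_that("k-spaced pair composition counts valid pairs only", {
  ck <- encode_cksaap(toy_window("AAAA"))
  expect_length(ck, 400L)
  expect_equal(unname(ck["CKSAAP.AA"]), 1)
  expect_equal(sum(ck), 1)

  ck2 <- encode_cksaap(toy_window("AKAK"))
  expect_equal(unname(ck2["CKSAAP.AK"]), 2 / 3)
  expect_equal(unname(ck2["CKSAAP.KA"]), 1 / 3)

  # masked endpoint excludes the pair from numerator and denominator
  ck3 <- encode_cksaap(toy_window("-KAK"))
  expect_equal(unname(ck3["CKSAAP.KA"]), 0.5)
  expect_equal(sum(ck3), 1)

  # spaced pairs: k = 1 skips one position
  ck4 <- encode_cksaap(toy_window("AKAK"), k = 1L)
  expect_equal(unname(ck4["CKSAAP.AA"]), 0.5)
  expect_equal(unname(ck4["CKSAAP.KK"]), 0.5)

  # all-gap window: defined as all zeros
  expect_equal(sum(encode_cksaap(toy_window("---"))), 0)

  set.seed(13)
  for (i in 1:10) {
    ck <- encode_cksaap(random_window())
    expect_equal(sum(ck), 1)
    expect_true(all(ck >= 0 & ck <= 1))
  }
})

test_that("window distance is the normalised substitution similarity", {
  m <- blosum62()
  # identical windows of the residue attaining max(M) on the diagonal
  ww <- homopolymer_window("W")
  expect_equal(knn_distance(ww, ww), 0)
  # a pair realising min(M) at every position gives distance 1
  worst <- which(m == attr(m, "min"), arr.ind = TRUE)[1, ]
  w1 <- homopolymer_window(rownames(m)[worst[1]])
  w2 <- homopolymer_window(colnames(m)[worst[2]])
  expect_equal(knn_distance(w1, w2), 1)
  # gaps score maximal dissimilarity position-wise
  wa <- homopolymer_window("A")
  wg <- toy_window(paste(c(rep("A", 12), "-"), collapse = ""))
  sim_aa <- (m["A", "A"] - attr(m, "min")) / (attr(m, "max") - attr(m, "min"))
  expect_equal(knn_distance(wa, wg), 1 - 12 * sim_aa / 13)

  expect_error(knn_distance(homopolymer_window("A", 5L), wa), "radius")
  set.seed(3)
  for (i in 1:20) {
    a <- random_window(); b <- random_window()
    d <- knn_distance(a, b)
    expect_equal(d, knn_distance(b, a))
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("nearest-neighbour scores match brute-force recomputation", {
  set.seed(17)
  fractions <- c(1/2, 1/4, 1/8, 1/16, 1/32)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    windows <- lapply(seq_len(n), function(i)
      random_window(protein_id = paste0("r", i), center = i))
    labels <- sample(c("positive", "negative"), n, replace = TRUE,
                     prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) labels[1:2] <- c("positive", "negative")
    ref <- knn_reference(windows, labels)
    # query in the reference (leave-one-out) and a fresh query
    for (q in list(windows[[3]], random_window(protein_id = "fresh"))) {
      for (ex in c(TRUE, FALSE)) {
        expect_equal(unname(encode_knn(q, ref, exclude_self = ex)),
                     brute_knn(q, windows, labels, fractions, ex))
      }
    }
  }

  # degenerate cases
  w <- homopolymer_window("A")
  ref1 <- knn_reference(list(w), "positive")
  expect_equal(unname(encode_knn(w, ref1, exclude_self = FALSE)), rep(1, 5))
  refneg <- knn_reference(list(w, homopolymer_window("W")),
                          c("negative", "negative"))
  expect_equal(unname(encode_knn(random_window(), refneg,
                                 exclude_self = FALSE)),
               rep(0, 5))
  expect_error(encode_knn(w, ref1, exclude_self = TRUE), "empty")
  expect_length(encode_knn(random_window(), ref1, exclude_self = FALSE), 5L)
})

test_that("auto-cross covariance equals a brute-force double loop", {
  # constant profile -> all covariances vanish
  expect_equal(unname(encode_acc(homopolymer_window("L"))), rep(0, 50))
  expect_length(encode_acc(random_window()), 50L)

  props <- atchley_factors()
  set.seed(29)
  for (rep in 1:5) {
    w <- random_window()
    out <- encode_acc(w)
    res <- w$residues[w$valid]
    prof <- vapply(props, function(tb)
      acetylsite:::property_lookup(tb, res), numeric(length(res)))
    nv <- length(res)
    for (g in 1:2) {
      for (u in 1:5) for (v in 1:5) {
        expected <- 0
        for (i in seq_len(nv - g)) {
          expected <- expected +
            (prof[i, u] - mean(prof[, u])) * (prof[i + g, v] - mean(prof[, v]))
        }
        nm <- paste0("ACC.g", g, ".Atchley-", u, ".Atchley-", v)
        expect_equal(unname(out[nm]), expected / (nv - g))
      }
    }
  }
  expect_error(encode_acc(toy_window("A-A--"), max_lag = 2L), "valid positions")
})

test_that("pseudo amino-acid composition is normalised and order-aware", {
  set.seed(41)
  for (rep in 1:5) {
    w <- random_window()
    out <- encode_pc_pseaac(w)
    expect_length(out, 22L)
    expect_equal(sum(out), 1)
    expect_true(all(out >= 0))
  }

  # lambda = 0 reduces to the plain composition of the window
  w <- toy_window("AAKKKLLLSSSSS")
  comp <- encode_pc_pseaac(w, lambda = 0L)
  expect_equal(unname(comp[paste0("PCPse.comp.", c("A", "K", "L", "S"))]),
               c(2, 3, 3, 5) / 13)

  # correlation factors match a brute-force double loop
  scales <- lapply(pseaac_scales(), function(tb) {
    v <- tb$values
    (v - mean(v)) / sqrt(sum((v - mean(v))^2) / 20)
  })
  w <- random_window()
  out <- encode_pc_pseaac(w, lambda = 2L, weight = 0.05)
  res <- w$residues[w$valid]
  nv <- length(res)
  theta <- numeric(2)
  for (g in 1:2) {
    acc <- 0
    for (i in seq_len(nv - g)) {
      acc <- acc + mean(vapply(scales, function(s)
        (s[[res[i]]] - s[[res[i + g]]])^2, numeric(1)))
    }
    theta[g] <- acc / (nv - g)
  }
  denom <- 1 + 0.05 * sum(theta)
  expect_equal(unname(out[c("PCPse.lambda1", "PCPse.lambda2")]),
               0.05 * theta / denom)
  expect_error(encode_pc_pseaac(toy_window("AK---"), lambda = 3L), "lambda")
})

test_that("property encoding averages over valid residues only", {
  w <- homopolymer_window("A")
  out <- encode_aaindex(w)
  kd <- aaindex_tables()[[1]]
  expect_equal(unname(out[paste0("AAindex.avg.", kd$name)]),
               unname(kd$values[["A"]]))
  # 10 averaged + 5 x 13 per-position features at L = 6
  expect_length(out, 75L)

  # one masked position: average over the 12 remaining values
  res <- c("-", rep("A", 11), "W")
  w2 <- toy_window(paste(res, collapse = ""))
  out2 <- encode_aaindex(w2)
  expect_equal(unname(out2[paste0("AAindex.avg.", kd$name)]),
               (11 * kd$values[["A"]] + kd$values[["W"]]) / 12)
  # masked per-position slots are zero
  expect_equal(unname(out2["AAindex.Atchley-1.j-6"]), 0)
  expect_equal(unname(out2[paste0("AAindex.Atchley-1.j+6")]),
               unname(atchley_factors()[[1]]$values[["W"]]))
})
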