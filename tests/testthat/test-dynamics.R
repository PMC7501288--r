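make_paired <- function(orf, mag, time, rna, protein) {
  data.frame(orf_id = orf, mag_id = mag, time_h = time,
             rna_molecules = rna, protein_molecules = protein,
             stringsAsFactors = FALSE)
}

test_that("ratio summaries report per-MAG medians and quartiles", {
  p <- make_paired("o1", "M1", 18, 2, 1000)
  r <- protein_rna_ratios(p, 18)
  expect_equal(r$summary$median, 500)
  expect_equal(r$summary$n_genes, 1)

  p3 <- make_paired(paste0("o", 1:3), "M1", 18, rep(1, 3),
                    c(100, 1000, 10000))
  expect_equal(protein_rna_ratios(p3, 18)$summary$median, 1000)
  # pooled bacterial summary
  p2 <- rbind(make_paired(paste0("a", 1:3), "M1", 18, 1, c(1, 2, 3) * 100),
              make_paired(paste0("b", 1:3), "M2", 18, 1, c(1, 2, 3) * 1000))
  r2 <- protein_rna_ratios(p2, 18,
                           domains = c(M1 = "bacterial", M2 = "bacterial"))
  pooled <- r2$summary[r2$summary$mag_id == "all_bacteria", ]
  expect_equal(pooled$n_genes, 6)
  expect_equal(pooled$median, median(c(100, 200, 300, 1000, 2000, 3000)))
  expect_error(protein_rna_ratios(make_paired("o", "M", 18, 0, 1), 18),
               "non-positive RNA")
  expect_error(protein_rna_ratios(p, 43), "no paired expression")
})

test_that("gene-wise PCC hits the exact limits and handles degeneracy", {
  t <- c(13, 18, 23, 28)
  rna <- c(1e5, 3e5, 2e5, 8e5)
  up <- make_paired("o1", "M1", t, rna, 2 * rna)
  expect_equal(genewise_pcc(up)$records$pcc, 1)
  # anti-linear in log space: log10(protein) = c - log10(rna)
  down <- make_paired("o1", "M1", t, rna, 1e12 / rna)
  expect_equal(genewise_pcc(down)$records$pcc, -1)
  # zero variance -> undefined, not forced +/-1
  flat <- make_paired("o1", "M1", t, rep(1e5, 4), 2 * rna)
  res <- genewise_pcc(flat)
  expect_true(is.na(res$records$pcc))
  expect_equal(res$n_undefined, 1)
  # fewer than 3 time points -> skipped and counted
  short <- make_paired("o2", "M1", t[1:2], rna[1:2], rna[1:2])
  expect_equal(genewise_pcc(short)$n_skipped, 1)
})

test_that("monomial fit recovers exact power-law data", {
  rna <- c(1e4, 1e5, 1e6, 1e7)
  fit <- fit_monomial(rna, 100 * rna^0.7)
  expect_equal(fit$k, 0.7, tolerance = 1e-9)
  expect_equal(fit$a_log10, 2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  fit1 <- fit_monomial(rna, rna)
  expect_equal(fit1$k, 1, tolerance = 1e-12)
  expect_equal(fit1$a_log10, 0, tolerance = 1e-12)
  expect_error(fit_monomial(rna[1:2], rna[1:2]), "at least 3")
  expect_error(fit_monomial(rep(10, 4), rna), "zero variance")
  expect_error(fit_monomial(c(0, rna[-1]), rna), "> 0")
})

test_that("OLS fit agrees with the normal-equations oracle", {
  # independent oracle: solve (X'X) b = X'y directly
  normal_eq <- function(x, y) {
    X <- cbind(1, x)
    solve(t(X) %*% X, t(X) %*% y)
  }
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:20, 1)
    lr <- stats::rnorm(n, 6, 1)
    lp <- 2.5 + 0.6 * lr + stats::rnorm(n, 0, 0.3)
    fit <- fit_monomial(10^lr, 10^lp)
    oracle <- normal_eq(lr, lp)
    expect_equal(fit$a_log10, oracle[1], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit$k, oracle[2], tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("protein fold change follows the monomial exponent", {
  expect_equal(predict_protein_change(1, 2), 2)
  expect_equal(predict_protein_change(0.5, 2), sqrt(2))
  # k = 0.5: a doubling of RNA is ~a 40% protein increase
  expect_equal(round(100 * (predict_protein_change(0.5, 2) - 1) / 10) * 10,
               40)
  expect_equal(predict_protein_change(0, 17.3), 1)
  expect_error(predict_protein_change(0.5, 0), "> 0")
})

test_that("cubic k trajectories interpolate and refuse extrapolation", {
  t4 <- c(13, 18, 23, 28)
  k4 <- c(0.8, 0.7, 0.65, 0.6)
  tr <- fit_k_trajectory(t4, k4)
  expect_equal(tr$fitted, k4, tolerance = 1e-9)
  expect_equal(max(abs(tr$residuals)), 0, tolerance = 1e-9)
  # constant k -> zero curvature
  trc <- fit_k_trajectory(c(13, 18, 23, 28, 33), rep(0.6, 5))
  expect_equal(unname(trc$coefficients),
               c(0.6, 0, 0, 0), tolerance = 1e-9)
  expect_error(fit_k_trajectory(t4[1:3], k4[1:3]), "at least 4")
  expect_error(tr$predict(50), "extrapolate")
  expect_equal(tr$predict(t4), k4, tolerance = 1e-9)
  # coefficient recovery from a known cubic plus small noise
  set.seed(9)
  tt <- seq(13, 43, by = 5)
  truth <- c(0.9, -0.02, 5e-4, -8e-6)
  hit <- 0
  for (i in 1:20) {
    kk <- truth[1] + truth[2] * tt + truth[3] * tt^2 + truth[4] * tt^3 +
      stats::rnorm(7, 0, 0.01)
    f <- stats::lm(kk ~ poly(tt, 3, raw = TRUE))
    se <- sqrt(diag(stats::vcov(f)))
    est <- fit_k_trajectory(tt, kk)$coefficients
    hit <- hit + all(abs(est - truth) <= 3 * se)
  }
  expect_gte(hit, 18)
})

test_that("Kendall tau matches exhaustive pair counting with ties", {
  # O(n^2) oracle: tau-b with tie corrections from concordant/discordant
  tau_oracle <- function(x, y) {
    n <- length(x)
    conc <- disc <- tx <- ty <- 0
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
        if (dx == 0 && dy == 0) next
        if (dx == 0) tx <- tx + 1
        else if (dy == 0) ty <- ty + 1
        else if (dx == dy) conc <- conc + 1
        else disc <- disc + 1
      }
    }
    (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
  }
  ids <- function(n) paste0("c", seq_len(n))
  x <- stats::setNames(c(5, 4, 3, 2, 1), ids(5))
  expect_equal(kendall_rank_preservation(x, x)$kendall_tau, 1)
  # alignment is by category name, not position
  expect_equal(kendall_rank_preservation(x, x[rev(names(x))])$kendall_tau, 1)
  y <- stats::setNames(1:5, ids(5))
  expect_equal(kendall_rank_preservation(x, y)$kendall_tau, -1)
  set.seed(13)
  for (i in 1:15) {
    n <- sample(5:50, 1)
    a <- stats::setNames(sample(1:8, n, replace = TRUE), ids(n))
    b <- stats::setNames(sample(1:8, n, replace = TRUE), ids(n))
    expect_equal(kendall_rank_preservation(a, b)$kendall_tau,
                 tau_oracle(a, b), tolerance = 1e-10)
  }
  bad <- stats::setNames(1:4, ids(4))
  expect_error(kendall_rank_preservation(x, bad), "category sets differ")
})

test_that("marker aggregation sums series and smooths cubically", {
  samples <- data.frame(sample_id = paste0("t", 1:7, "A"),
                        time_h = seq(13, 43, by = 5), replicate = "A")
  catalog <- data.frame(orf_id = c("o1", "o2"), mag_id = "M1",
                        orfg_id_mt = c("o1", "o2"),
                        orfg_id_mp = c("o1", "o2"),
                        stringsAsFactors = FALSE)
  tt <- samples$time_h
  # series lying exactly on a cubic in log10 space
  y1 <- 10^(6 + 0.05 * tt - 1e-3 * tt^2 + 1e-5 * tt^3) - 1
  mt <- data.frame(orfg_id = rep(c("o1", "o2"), each = 7),
                   sample_id = rep(samples$sample_id, 2),
                   molecules_sample = c(y1, 2 * y1))
  single <- aggregate_pathway_markers(mt, list(pw = "o1"), catalog, samples)
  expect_equal(single$molecules, y1)
  expect_equal(single$smooth_log10, log10(y1 + 1), tolerance = 1e-8)
  both <- aggregate_pathway_markers(mt, list(pw = c("o1", "o2")),
                                    catalog, samples)
  expect_equal(both$molecules, 3 * y1)
  expect_warning(
    miss <- aggregate_pathway_markers(mt, list(pw = c("o1", "zz")),
                                      catalog, samples),
    "unknown marker")
  expect_equal(attr(miss, "n_unknown_markers"), 1L)
  expect_equal(miss$molecules, y1)
})
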