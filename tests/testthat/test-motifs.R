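test_that("fit_activities recovers a planted shift on indicator motifs", {
  # disjoint target sets; targets of motif 1 shifted by +delta in cell 2
  N <- cbind(m1 = c(1, 1, 1, 0, 0, 0, 0, 0), m2 = c(0, 0, 0, 1, 1, 1, 0, 0))
  E <- matrix(0, 8, 3)
  delta <- 1.7
  E[1:3, 2] <- delta
  am <- fit_activities(E, N, lambda = 0)
  # QR least-squares oracle on the standardized design
  Ns <- scale(N)
  Ec <- E - rowMeans(E)
  A_oracle <- qr.solve(Ns, Ec)
  A_oracle <- A_oracle - rowMeans(A_oracle)
  expect_equal(unname(am$A), unname(A_oracle), tolerance = 1e-8)
  # the planted cell stands out on motif 1; motif-1 activity is symmetric
  # in the untouched cells
  a1 <- am$A["m1", ]
  expect_gt(a1[2], max(a1[c(1, 3)]))
  expect_equal(a1[1], a1[3], tolerance = 1e-10)
  expect_equal(unname(rowMeans(am$A)), c(0, 0), tolerance = 1e-10)
})

test_that("fit_activities equals an independent lm() solve at lambda 0", {
  set.seed(30)
  for (rep_i in 1:3) {
    G <- 40; m <- 5; n <- 7
    N <- matrix(rpois(G * m, 1.5), G, m,
                dimnames = list(NULL, paste0("m", 1:m)))
    N[1, ] <- N[1, ] + 1  # avoid all-zero columns
    E <- matrix(rnorm(G * n), G, n)
    am <- fit_activities(E, N, lambda = 0)
    Ns <- scale(N)
    Ec <- E - rowMeans(E)
    fits <- lapply(seq_len(n), function(c) lm(Ec[, c] ~ Ns - 1))
    A_lm <- vapply(fits, coef, numeric(m))
    A_lm <- A_lm - rowMeans(A_lm)
    expect_equal(unname(am$A), unname(A_lm), tolerance = 1e-8)
    se_lm <- vapply(fits, function(f)
      summary(f)$coefficients[, "Std. Error"], numeric(m))
    expect_equal(unname(am$se), unname(se_lm), tolerance = 1e-6)
  }
})

test_that("fit_activities validates penalties and rank", {
  N <- cbind(a = c(1, 2, 1, 0), b = c(2, 4, 2, 0))  # collinear columns
  E <- matrix(rnorm(8), 4, 2)
  expect_error(fit_activities(E, N, lambda = -1), "nonnegative")
  expect_error(fit_activities(E, N, lambda = 0), "rank deficient")
  expect_silent(fit_activities(E, N, lambda = 0.5))
  # centered expression (all-zero deviation) gives zero activities
  E0 <- matrix(5, 4, 3)
  N2 <- cbind(a = c(1, 0, 2, 0), b = c(0, 1, 0, 3))
  am <- fit_activities(E0, N2, lambda = 0)
  expect_equal(max(abs(am$A)), 0, tolerance = 1e-12)
  expect_warning(fit_activities(E0, cbind(N2, z = 0), lambda = 0), "zero")
})

test_that("activity z-scores follow the RMS definition and invariances", {
  A <- rbind(m1 = c(0, 0, 0), m2 = c(1, -1, 1), m3 = c(2, 2, -2))
  se <- matrix(1, 3, 3, dimnames = list(rownames(A), NULL))
  am <- structure(list(A = A, se = se), class = "activity_matrix")
  z <- activity_zscores(am)
  expect_equal(unname(z), c(0, 1, 2))
  # scaling A and dA together leaves z unchanged
  am2 <- structure(list(A = A * 13, se = se * 13), class = "activity_matrix")
  expect_equal(activity_zscores(am2), z)
})

test_that("profile_std is the population SD of the binned means", {
  expect_equal(profile_std(c(1, 1, 1, 1)), 0)
  expect_equal(profile_std(c(0, 0.01)), 0.005)
  ramp <- seq(0, 1, length.out = 50)
  expect_equal(profile_std(ramp), sqrt(mean((ramp - mean(ramp))^2)))
  expect_error(profile_std(c(1)), "2 bins")
})

test_that("lagged_correlation finds constructed shifts at the exact bin", {
  t <- seq_len(60)
  base <- sin(t / 6)
  self <- lagged_correlation(base, base)
  expect_equal(self$peak_rho, 1)
  expect_equal(self$peak_lag, 0L)
  expect_equal(self$role, "activator")
  neg <- lagged_correlation(base, -base)
  expect_equal(neg$peak_rho, -1)
  expect_equal(neg$role, "repressor")
  # activity = expression shifted 7 bins later
  shifted <- c(rep(base[1], 7), base[seq_len(53)])
  lc <- lagged_correlation(base, shifted, max_lag = 15)
  expect_equal(lc$peak_lag, 7L)
  expect_gt(abs(lc$peak_rho), 0.99)
  # swapping the profiles negates the peak lag, preserves the peak rho
  lc2 <- lagged_correlation(shifted, base, max_lag = 15)
  expect_equal(lc2$peak_lag, -7L)
  expect_equal(abs(lc2$peak_rho), abs(lc$peak_rho), tolerance = 1e-12)
})

test_that("select_differential applies the three thresholds jointly", {
  mk_prof <- function(x) data.frame(t = seq_along(x), mean = x)
  flat <- mk_prof(rep(0, 20))
  rise <- mk_prof(seq(0, 0.1, length.out = 20))
  lc_hi <- structure(list(peak_rho = 0.9, peak_lag = 1L, role = "activator"),
                     class = "lagged_correlation")
  lc_lo <- structure(list(peak_rho = 0.2, peak_lag = 0L, role = "none"),
                     class = "lagged_correlation")
  z <- c(good = 2.0, border = 1.39, nocorr = 3.0)
  profiles <- list(good = list(EC = rise, XMD = flat),
                   border = list(EC = rise, XMD = rise),
                   nocorr = list(EC = rise, XMD = flat))
  cors <- list(good = list(EC = lc_hi, XMD = lc_hi),
               border = list(EC = lc_hi, XMD = lc_hi),
               nocorr = list(EC = lc_lo, XMD = lc_lo))
  rep_df <- select_differential(z, profiles, cors)
  expect_equal(unique(rep_df$motif), "good")
  expect_equal(rep_df$fate, "EC")          # flat XMD profile fails std
  expect_equal(rep_df$specificity, "EC")
  expect_equal(attr(rep_df, "categories")[["EC"]], 1L)
  # z = 1.39 fails the >= 1.4 boundary everywhere
  expect_false("border" %in% rep_df$motif)
  # tightening any threshold never adds a motif
  tighter <- select_differential(z, profiles, cors, z_min = 3.5)
  expect_true(all(paste(tighter$motif, tighter$fate) %in%
                    paste(rep_df$motif, rep_df$fate)))
})

test_that("motifs at the exact thresholds are included (>= semantics)", {
  mk_prof <- function(x) data.frame(t = seq_along(x), mean = x)
  two <- mk_prof(rep(c(0, 0.008), each = 10))  # population SD exactly 0.004
  lc <- structure(list(peak_rho = 0.7, peak_lag = 0L, role = "activator"),
                  class = "lagged_correlation")
  rep_df <- select_differential(c(m = 1.4), list(m = list(EC = two)),
                                list(m = list(EC = lc)))
  expect_equal(nrow(rep_df), 1L)
})

test_that("read_motif_targets aligns genes and maps TFs", {
  d <- withr::local_tempdir()
  write.table(data.frame(gene = c("g1", "g3", "g9"),
                         motif = c("mA", "mA", "mB"), count = c(2, 1, 5)),
              file.path(d, "sites.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(data.frame(motif = c("mA", "mB"), tf_gene = c("g1", "g2")),
              file.path(d, "map.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  mt <- read_motif_targets(file.path(d, "sites.tsv"),
                           gene_ids = c("g1", "g2", "g3"),
                           tf_map_path = file.path(d, "map.tsv"))
  expect_equal(mt$N["g1", "mA"], 2)
  expect_equal(mt$N["g3", "mA"], 1)
  expect_equal(unname(mt$N[, "mB"]), c(0, 0, 0))  # g9 outside the universe
  expect_equal(mt$tf_map[["mA"]], "g1")
})
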