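qspec <- function(pmz, frags, rt = NA_real_, mode = "HILIC", id = NULL)
  spectrum(pmz, frags, rt = rt, mode = mode, id = id)

test_that("candidate search applies ppm and mode-specific RT windows", {
  lib <- list(qspec(300.0030, cbind(100, 1), rt = 100, id = "in10ppm"),
              qspec(300.0060, cbind(100, 1), rt = 100, id = "out20ppm"),
              qspec(300.0000, cbind(100, 1), rt = 140, id = "rt_out"),
              qspec(300.0000, cbind(100, 1), id = "public_no_rt"))
  q <- qspec(300.0000, cbind(100, 1), rt = 105, mode = "HILIC")
  idx <- candidate_search(q, lib)
  got <- vapply(lib[idx], `[[`, "", "id")
  expect_setequal(got, c("in10ppm", "public_no_rt"))
  # RPLC window is tighter: 20 s
  q_rplc <- qspec(300.0000, cbind(100, 1), rt = 105, mode = "RPLC")
  lib2 <- list(qspec(300.0000, cbind(100, 1), rt = 130, id = "delta25"))
  expect_length(candidate_search(q_rplc, lib2), 0)
  expect_length(candidate_search(q, lib2), 1)
  expect_length(candidate_search(q, list()), 0)
})

test_that("candidate search returns exactly the constructed in-window entries", {
  set.seed(6)
  base <- 400
  in_win <- c(400.0000, 400.0040, 399.9960)      # 0, 10, 10 ppm
  out_win <- base * (1 + sample(c(-1, 1), 47, TRUE) *
                       runif(47, 30e-6, 500e-6)) # >= 30 ppm away
  lib <- c(lapply(seq_along(in_win), function(i)
             qspec(in_win[i], cbind(100, 1), id = paste0("in", i))),
           lapply(seq_along(out_win), function(i)
             qspec(out_win[i], cbind(100, 1), id = paste0("out", i))))
  q <- qspec(400.0000, cbind(100, 1))
  got <- vapply(lib[candidate_search(q, lib)], `[[`, "", "id")
  expect_setequal(got, c("in1", "in2", "in3"))
})

test_that("forward dot product matches the closed-form hand calculation", {
  # identical spectra score exactly 1
  s <- qspec(200, cbind(c(100, 150, 200), c(5, 1, 9)))
  expect_equal(as.numeric(forward_dot_product(s, s)), 1, tolerance = 1e-12)

  # disjoint fragments score 0
  a <- qspec(200, cbind(100, 5))
  b <- qspec(200, cbind(150, 5))
  expect_equal(as.numeric(forward_dot_product(a, b)), 0)

  # hand case: query {100:4, 200:9}, reference {100:1, 300:4}
  # sqrt weights: wq = (2, 3), wr = (1, 2); only m/z 100 pairs
  # score = (2*1)^2 / ((4+9) * (1+4)) = 4/65
  q <- qspec(200, cbind(c(100, 200), c(4, 9)))
  r <- qspec(200, cbind(c(100, 300), c(1, 4)))
  sc <- forward_dot_product(q, r)
  expect_equal(as.numeric(sc), 4 / 65, tolerance = 1e-12)
  expect_equal(as.numeric(sc),
               oracle_dot_product(c(2, 3), c(1, 2),
                                  matrix(c(1, 1), 1)), tolerance = 1e-12)
  expect_equal(attr(sc, "n_matched"), 1L)

  expect_error(forward_dot_product(qspec(200, cbind(100, 1)[0, , drop = FALSE]),
                                   r), "empty")
})

test_that("dot product is symmetric, rescale-invariant and in [0, 1]", {
  set.seed(12)
  for (i in 1:20) {
    # fully matched pair: same m/z grid, different intensities
    nf <- sample(2:6, 1)
    mz <- sort(runif(nf, 100, 500))
    q <- qspec(300, cbind(mz, runif(nf, 1, 100)))
    r <- qspec(300, cbind(mz, runif(nf, 1, 100)))
    s1 <- as.numeric(forward_dot_product(q, r))
    s2 <- as.numeric(forward_dot_product(r, q))
    expect_gte(s1, 0); expect_lte(s1, 1)
    expect_equal(s1, s2, tolerance = 1e-9)  # symmetric when fully matched
    # uniform intensity rescaling changes nothing
    q5 <- qspec(300, cbind(q$fragments[, 1], 5 * q$fragments[, 2]))
    expect_equal(as.numeric(forward_dot_product(q5, r)), s1,
                 tolerance = 1e-12)
    # partially overlapping random pair: score stays in [0, 1] and
    # tightening the tolerance never increases it
    r2 <- qspec(300, cbind(sort(c(mz[1] * (1 + 8e-6),
                                  runif(nf - 1, 100, 500))),
                           runif(nf, 1, 100)))
    s3 <- as.numeric(forward_dot_product(q, r2))
    expect_gte(s3, 0); expect_lte(s3, 1)
    tight <- forward_dot_product(q, r2, match_config(fragment_ppm = 1))
    expect_lte(as.numeric(tight), s3 + 1e-12)
  }
})

test_that("annotation assigns MSI levels by library provenance and score", {
  frags <- cbind(c(97.0, 145.1, 271.2), c(10, 40, 100))
  inhouse <- list(qspec(447.2, frags, rt = 120, id = "estriol-16-glucuronide"))
  public <- list(qspec(447.2, frags, id = "estriol glucuronide (MoNA)"),
                 qspec(433.2, cbind(c(97.0, 255.1), c(10, 50)),
                       id = "weak match"))
  q_good <- qspec(447.2, frags, rt = 125)
  q_part <- qspec(433.2, cbind(c(97.0, 180.0), c(10, 90)), rt = 200)

  res <- annotate_features(
    c("feat1", "feat2", "feat3", "feat4"),
    list(feat1 = list(q_good), feat2 = list(q_part),
         feat3 = list()),
    inhouse_library = inhouse, public_library = public,
    putative_ids = c(feat3 = "putative urocanate"))
  expect_equal(res$msi_level, c(1L, 4L, 3L, 4L))
  expect_equal(res$library_id[1], "estriol-16-glucuronide")
  expect_equal(res$score[1], 1)
  expect_true(is.na(res$library_id[2]))   # score below 0.4 -> unknown
  expect_equal(res$library_id[3], "putative urocanate")
  expect_true(is.na(res$library_id[4]))

  # public-only match above threshold -> level 2; multiple spectra use the max
  q_half <- qspec(447.2, cbind(c(97.0, 145.1), c(10, 40)))
  res2 <- annotate_features("featX",
                            list(featX = list(q_half, q_good)),
                            public_library = public)
  expect_equal(res2$msi_level, 2L)
  expect_equal(res2$score, 1)
})

test_that("MSP and MGF round-trips preserve spectra", {
  sp <- list(qspec(447.2, cbind(c(97.0, 145.1), c(10.5, 40)), rt = 120.5,
                   id = "demo-standard"),
             qspec(301.1, cbind(c(100.1, 150.2, 200.3), c(1, 2, 3)),
                   id = "demo-public"))
  msp <- withr::local_tempfile(fileext = ".msp")
  write_msp(sp, msp)
  back <- read_msp(msp)
  expect_length(back, 2)
  expect_equal(back[[1]]$precursor_mz, 447.2)
  expect_equal(back[[1]]$rt, 120.5)
  expect_equal(back[[1]]$id, "demo-standard")
  expect_equal(back[[2]]$fragments[, "mz"], c(100.1, 150.2, 200.3),
               ignore_attr = TRUE)
  expect_true(is.na(back[[2]]$rt))

  mgf <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=demo", "PEPMASS=447.2", "RTINSECONDS=120.5",
               "97.0 10.5", "145.1 40", "END IONS"), mgf)
  sp2 <- read_mgf(mgf)
  expect_length(sp2, 1)
  expect_equal(sp2[[1]]$precursor_mz, 447.2)
  expect_equal(sp2[[1]]$fragments[, "intensity"], c(10.5, 40),
               ignore_attr = TRUE)
})

test_that("spectrum constructor enforces the fragment contract", {
  expect_error(spectrum(-1, cbind(100, 1)), "positive")
  expect_error(spectrum(100, cbind(c(100, 200), c(-1, 1))), "negative")
  s <- spectrum(100, cbind(c(200, 100), c(1, 2)))
  expect_equal(s$fragments[, "mz"], c(100, 200), ignore_attr = TRUE)
})
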