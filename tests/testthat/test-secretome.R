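test_that("quantification reproduces rendered densities within 1%", {
  lay <- cytokine_array_layout()
  g <- generate_cytokine_array(lay, fold_changes = c(CK2 = 2.5), seed = 4)
  ev <- quantify_array(g$stack, lay, channel = "ev")
  truth <- g$truth$params
  for (a in truth$analytes) {
    rendered <- truth$ev_density[[a]] + truth$background_level
    expect_equal(unname(ev$means[a]), rendered, tolerance = 0.01)
  }
  expect_equal(ev$background, truth$background_level, tolerance = 1e-9)
  expect_equal(ev$reference, truth$reference_density + truth$background_level,
               tolerance = 0.01)
})

test_that("a blank membrane reads background everywhere", {
  lay <- cytokine_array_layout()
  img <- matrix(0.08, 280, 280)
  arr <- quantify_array(img, lay, refine_registration = FALSE)
  expect_true(all(abs(arr$means - arr$background) < 1e-12))
})

test_that("the 180-degree rotation flag restores the layout registration", {
  lay <- cytokine_array_layout()
  g <- generate_cytokine_array(lay, fold_changes = c(CK7 = 4), seed = 9)
  img <- get_plane(g$stack, "mutant")
  flipped <- img[rev(seq_len(nrow(img))), rev(seq_len(ncol(img)))]
  a1 <- quantify_array(img, lay)
  a2 <- quantify_array(flipped, lay, rotated_180 = TRUE)
  expect_equal(a2$means, a1$means, tolerance = 1e-12)
  expect_equal(a2$background, a1$background, tolerance = 1e-12)
})

test_that("normalization is exact on hand-computable membranes", {
  # oracle: hand arithmetic — ((900-100)/(500-100)) * (1600/2000) = 1.6
  ev <- manual_array(c(IL6 = 500), background = 100, reference = 1600)
  mut <- manual_array(c(IL6 = 900), background = 100, reference = 2000)
  expect_equal(as.numeric(normalize_to_ev(mut, ev)),
               (900 - 100) / (500 - 100) * (1600 / 2000))
  # identical membranes -> exactly 1
  expect_equal(as.numeric(normalize_to_ev(ev, ev)), 1)
  # doubled signal above background, equal references -> 2
  ev2 <- manual_array(c(a = 30, b = 50), background = 10, reference = 7)
  mut2 <- manual_array(c(a = 50, b = 90), background = 10, reference = 7)
  expect_equal(as.numeric(normalize_to_ev(mut2, ev2)), c(2, 2))
})

test_that("normalization matches the arithmetic oracle on random membranes", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    nm <- paste0("c", seq_len(n))
    bg_e <- runif(1, 0, 5); bg_m <- runif(1, 0, 5)
    ev <- manual_array(stats::setNames(bg_e + runif(n, 0.5, 50), nm),
                       background = bg_e, reference = runif(1, 1, 40))
    mut <- manual_array(stats::setNames(bg_m + runif(n, 0.5, 50), nm),
                        background = bg_m, reference = runif(1, 1, 40))
    got <- normalize_to_ev(mut, ev)
    want <- ((mut$means - mut$background) / (ev$means - ev$background)) *
      (ev$reference / mut$reference)
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
  }
})

test_that("normalization is invariant to per-membrane exposure scaling", {
  nm <- paste0("c", 1:6)
  ev <- manual_array(stats::setNames(2 + (1:6), nm), background = 2,
                     reference = 9)
  mut <- manual_array(stats::setNames(2 + 2 * (1:6), nm), background = 2,
                      reference = 8)
  base <- normalize_to_ev(mut, ev)
  k <- 3.7
  mut_k <- manual_array(mut$means * k, mut$background * k, mut$reference * k)
  expect_equal(as.numeric(normalize_to_ev(mut_k, ev)), as.numeric(base),
               tolerance = 1e-12)
  # and through the full render path with unequal exposures
  lay <- cytokine_array_layout()
  g <- generate_cytokine_array(lay, fold_changes = c(CK5 = 3), seed = 2,
                               exposure = c(1, 2.4))
  rel <- normalize_to_ev(quantify_array(g$stack, lay, channel = "mutant"),
                         quantify_array(g$stack, lay, channel = "ev"))
  expect_equal(unname(rel["CK5"]), 3, tolerance = 1e-6)
})

test_that("non-positive EV signal is flagged undefined, not fabricated", {
  ev <- manual_array(c(a = 5, b = 20), background = 5, reference = 3)
  mut <- manual_array(c(a = 9, b = 30), background = 4, reference = 3)
  expect_warning(rel <- normalize_to_ev(mut, ev), "below background")
  expect_true(is.na(rel["a"]))
  expect_false(is.na(rel["b"]))
  expect_identical(attr(rel, "undefined"), "a")
})

test_that("tidy CSV export round-trips the normalized values", {
  lay <- cytokine_array_layout()
  g <- generate_cytokine_array(lay, fold_changes = c(CK1 = 2), seed = 6)
  ev <- quantify_array(g$stack, lay, channel = "ev")
  mut <- quantify_array(g$stack, lay, channel = "mutant")
  path <- tempfile(fileext = ".csv")
  df <- write_array_csv(mut, ev, path)
  back <- utils::read.csv(path)
  expect_equal(back$relative_secretion, df$relative_secretion)
  expect_equal(back$relative_secretion[back$cytokine == "CK1"], 2,
               tolerance = 1e-9)
})
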