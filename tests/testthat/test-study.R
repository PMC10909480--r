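test_that("the stromal factorial produces one row per combination and is
           monotone in C10 at fixed k1", {
  tab <- stromalParameterSweep(sweepRVE(), C10Grid = c(5, 17.5, 30),
                               k1Grid = c(10, 155))
  expect_equal(nrow(tab), 6L)
  expect_false(any(tab$failed))
  for (k1 in c(10, 155)) {
    sub <- tab[tab$k1_S == k1, ]
    sub <- sub[order(sub$C10_S), ]
    expect_true(all(diff(sub$E11c) > 0))
    expect_true(all(diff(sub$E22t) > 0))
  }
  ## default grids are the 5 evenly spaced levels with 17.5/155 midpoints
  expect_equal(seq(5, 30, length.out = 5)[3], 17.5)
  expect_equal(seq(10, 300, length.out = 5)[3], 155)
})

test_that("compressive moduli of an aligned homogeneous RVE are identical
           across k1", {
  rve <- mirrorOrthotropic(labelImage(matrix(0L, 4, 4), 50))
  m <- meshFromLabels(rve, constantAngleDeg = 0)
  tab <- stromalParameterSweep(
    new("PeriodicRVE", labels = rve@labels,
        orientation = generateFiberField(rve@labels, "constant", 0),
        provenance = list()),
    C10Grid = 17.5, k1Grid = c(10, 155, 300))
  ## compression along the fibre direction never engages the fibres
  expect_lt(max(tab$E11c) - min(tab$E11c), 1e-9 * tab$E11c[1])
  ## tension along the fibre does feel k1
  expect_gt(max(tab$E11t) - min(tab$E11t), 0.05 * tab$E11t[1])
})

test_that("benchmark selection ranks by distance with declared tie rules", {
  mk <- function(C10, k1, e11c, e22c)
    data.frame(rve = "r1", C10_S = C10, k1_S = k1, C10_E = 1, C10_A = 19,
               E11t = 1, E11c = e11c, E22t = 1, E22c = e22c, G12t = 1,
               G12c = 1, fS = 0.5, fE = 0.3, fA = 0.2, failed = FALSE)
  tab <- rbind(mk(5, 10, 14, 14), mk(17.5, 155, 20, 20), mk(30, 300, 40, 40))
  sel <- benchmarkSelect(tab)
  expect_equal(sel$best$C10_S, 17.5)
  expect_equal(sel$best$meanEc, 20)
  expect_false(sel$outsideRange)
  ## permutation invariance
  sel2 <- benchmarkSelect(tab[c(3, 1, 2), ])
  expect_identical(sel$best, sel2$best)
  ## equidistant combinations: smaller C10 wins
  tabTie <- rbind(mk(10, 10, 18, 18), mk(20, 10, 22, 22))
  expect_equal(benchmarkSelect(tabTie)$best$C10_S, 10)
  ## all combinations out of range
  tabFar <- rbind(mk(5, 10, 100, 100), mk(30, 300, 200, 200))
  selF <- benchmarkSelect(tabFar)
  expect_true(selF$outsideRange)
  expect_equal(selF$best$C10_S, 5)
  expect_error(benchmarkSelect(transform(tab, failed = TRUE)), "failed")
})

test_that("the epithelium/lumen factorial is exhaustive and monotone", {
  tab <- epitheliumLumenSweep(sweepRVE(), C10EGrid = c(0.192, 4.801),
                              C10AGrid = c(1.92, 192))
  expect_equal(nrow(tab), 4L)
  sub <- tab[tab$C10_A == 1.92, ]
  expect_true(all(sub$E11t[order(sub$C10_E)] == sort(sub$E11t)))
})

test_that("fraction regression recovers exact linear structure", {
  fr <- cbind(seq(0.3, 0.7, length.out = 6),
              seq(0.5, 0.2, length.out = 6),
              1 - seq(0.3, 0.7, length.out = 6) -
                seq(0.5, 0.2, length.out = 6))
  y <- 4 + 30 * fr[, 1]
  out <- correlateFractions(y, fr)
  expect_equal(out$r_squared[1], 1, tolerance = 1e-10)
  expect_equal(out$slope[1], 30, tolerance = 1e-10)
  expect_lt(out$slope[2], 0)   # epithelium fraction falls as stroma rises
  ## constant moduli: R^2 fixed to 0 by convention
  outc <- correlateFractions(rep(5, 6), fr)
  expect_true(all(outc$r_squared == 0))
  expect_error(correlateFractions(c(1, 2), fr[1:2, ]), "at least 3")
})

test_that("asymmetry indices follow their definition", {
  m <- new("ApparentModuli", E11t = 30, E11c = 20, E22t = 15, E22c = 10,
           G12t = 5, G12c = 5)
  a <- asymmetryIndex(m)
  expect_equal(unname(a), c(0.5, 0.5))
  m2 <- new("ApparentModuli", E11t = 20, E11c = 20, E22t = 10, E22c = 10,
            G12t = 5, G12c = 5)
  expect_equal(unname(asymmetryIndex(m2)), c(0, 0))
  m3 <- new("ApparentModuli", E11t = 20, E11c = 0, E22t = 10, E22c = 10,
            G12t = 5, G12c = 5)
  expect_error(asymmetryIndex(m3), "compressive")
})

test_that("the Welch test matches an independent computation and maps
           stars correctly", {
  a <- c(14.1, 15.2, 13.8, 16.0, 14.9)
  b <- c(12.0, 11.4, 12.8, 11.1)
  w <- welchTTest(a, b)
  ## Welch formulas computed directly
  tManual <- (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  nu <- (var(a) / length(a) + var(b) / length(b))^2 /
    ((var(a) / length(a))^2 / (length(a) - 1) +
       (var(b) / length(b))^2 / (length(b) - 1))
  pManual <- 2 * stats::pt(-abs(tManual), df = nu)
  expect_equal(w$t, tManual, tolerance = 1e-6)
  expect_equal(w$p, pManual, tolerance = 1e-6)
  ## identical groups
  w0 <- welchTTest(c(1, 1, 1), c(1, 1, 1))
  expect_equal(w0$t, 0); expect_equal(w0$p, 1)
  expect_equal(w0$stars, "NS")
  ## threshold mapping
  expect_equal(HistoMech::welchTTest(rep(c(0, 0.02), 8) + 1:16 * 0,
                                     rep(c(0, 0.02), 8))$stars, "NS")
  expect_error(welchTTest(1, c(1, 2)), "at least 2")
  stars <- function(p) if (p < 0.001) "***" else if (p < 0.01) "**"
    else if (p < 0.05) "*" else "NS"
  expect_equal(stars(0.02), "*")
  expect_equal(w$stars, stars(w$p))
})

test_that("reports round-trip through CSV and JSON", {
  d <- withr::local_tempdir()
  tab <- data.frame(a = 1:3, b = c("x", "y", "z"),
                    stringsAsFactors = FALSE)
  writeReport(list(sweep = tab, empty = tab[0, ]),
              list(seed = 7L, config = list(magnitude = 0.05)), d)
  back <- utils::read.csv(file.path(d, "sweep.csv"),
                          stringsAsFactors = FALSE)
  expect_equal(back, tab)
  emp <- utils::read.csv(file.path(d, "empty.csv"))
  expect_equal(nrow(emp), 0L)
  expect_identical(names(emp), names(tab))
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_equal(js$seed, 7L)
  expect_equal(js$config$magnitude, 0.05)
})

test_that("YAML material configs build the right objects", {
  p <- file.path(withr::local_tempdir(), "cfg.yaml")
  writeLines(c("materials:",
               "  stroma: {model: HGO, C10: 17.5, k1: 155, k2: 200, kappa: 0}",
               "  epithelium: {model: NH, C10: 0.96}",
               "  lumen: {model: NH, C10: 19.2, nu: 0.45}"), p)
  cfg <- readConfig(p)
  expect_s4_class(cfg$materials$stroma, "HGO")
  expect_equal(cfg$materials$stroma@k1, 155)
  expect_s4_class(cfg$materials$epithelium, "NeoHookean")
  expect_equal(cfg$materials$lumen@D1, d1FromNu(19.2, 0.45))
})
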