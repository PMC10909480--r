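#' @include AllClasses.R fe.R
NULL

moduliRow <- function(m) {
  data.frame(E11t = m@E11t, E11c = m@E11c, E22t = m@E22t, E22c = m@E22c,
             G12t = m@G12t, G12c = m@G12c)
}

prepModels <- function(rves, coarsen) {
  if (is(rves, "PeriodicRVE")) rves <- list(rves)
  ids <- names(rves)
  if (is.null(ids)) ids <- paste0("rve", seq_along(rves))
  lapply(seq_along(rves), function(k) {
    r <- rves[[k]]
    list(id = ids[k], model = meshFromLabels(r, coarsen = coarsen),
         fractions = areaFractions(r@labels))
  })
}

sweepCore <- function(prep, materialsFor, grid, ...) {
  rows <- vector("list", nrow(grid) * length(prep))
  n <- 0L
  for (p in prep) {
    ctx <- feContext(p$model)
    for (g in seq_len(nrow(grid))) {
      n <- n + 1L
      mats <- materialsFor(grid[g, ])
      rows[[n]] <- tryCatch({
        res <- solveAllCases(p$model, mats, ...)
        cbind(data.frame(rve = p$id), grid[g, , drop = FALSE],
              moduliRow(apparentModuli(res)),
              data.frame(fS = p$fractions[1], fE = p$fractions[2],
                         fA = p$fractions[3], failed = FALSE))
      }, error = function(e)
        cbind(data.frame(rve = p$id), grid[g, , drop = FALSE],
              data.frame(E11t = NA, E11c = NA, E22t = NA, E22c = NA,
                         G12t = NA, G12c = NA, fS = p$fractions[1],
                         fE = p$fractions[2], fA = p$fractions[3],
                         failed = TRUE)))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

#' Stromal parameter sweep (C10 x k1 factorial)
#'
#' Full factorial over the stromal matrix stiffness C10 and fibre stiffness
#' k1 (defaults: 5 evenly spaced levels spanning the literature ranges
#' 5-30 kPa and 10-300 kPa, making 17.5 and 155 kPa the grid midpoints and
#' 25 combinations in total), with the epithelial and lumen materials held
#' at fixed benchmark values. Six load cases are solved per combination and
#' RVE; failed solves are flagged, not dropped.
#'
#' @param rves a \linkS4class{PeriodicRVE} or list of them
#' @param C10Grid,k1Grid stromal parameter levels (kPa)
#' @param fixed named list with \code{epithelium} and \code{lumen}
#'   materials (default: geometric mid-range neo-Hookean values)
#' @param k2,kappa,nu remaining stromal HGO parameters
#' @param coarsen mesh coarsening factor
#' @param ... passed to \code{\link{solveAllCases}}
#' @return data.frame, one row per RVE x combination
#' @export
stromalParameterSweep <- function(rves,
                                  C10Grid = seq(5, 30, length.out = 5),
                                  k1Grid = seq(10, 300, length.out = 5),
                                  fixed = NULL, k2 = 200, kappa = 0,
                                  nu = 0.49, coarsen = 1L, ...) {
  if (is.null(fixed)) {
    dm <- defaultMaterials(nu)
    fixed <- dm[c("epithelium", "lumen")]
  }
  grid <- expand.grid(C10_S = C10Grid, k1_S = k1Grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$C10_E <- fixed$epithelium@C10
  grid$C10_A <- fixed$lumen@C10
  prep <- prepModels(rves, coarsen)
  materialsFor <- function(row)
    list(stroma = hgo(row$C10_S, row$k1_S, k2, kappa, nu = nu),
         epithelium = fixed$epithelium, lumen = fixed$lumen)
  sweepCore(prep, materialsFor, grid, ...)
}

#' Select the stromal combination matching a compressive benchmark
#'
#' Ranks (C10_S, k1_S) combinations by the distance of their mean apparent
#' compressive modulus (mean of E11c and E22c over RVEs) from the literature
#' target (20 +/- 5 kPa by default). Ties break toward smaller C10, then
#' smaller k1. The selection is independent of row order.
#'
#' @param table output of \code{\link{stromalParameterSweep}}
#' @param targetKpa benchmark compressive modulus (kPa)
#' @param halfwidthKpa half-width of the acceptance band (kPa)
#' @return list: \code{best} (one-row data.frame with meanEc),
#'   \code{withinRange} (all combinations inside the band),
#'   \code{outsideRange} flag
#' @export
benchmarkSelect <- function(table, targetKpa = 20, halfwidthKpa = 5) {
  ok <- !table$failed
  if (!any(ok)) stop("all sweep rows are flagged failed")
  t2 <- table[ok, ]
  agg <- stats::aggregate(cbind(E11c, E22c) ~ C10_S + k1_S, data = t2,
                          FUN = mean)
  agg$meanEc <- (agg$E11c + agg$E22c) / 2
  agg$dist <- abs(agg$meanEc - targetKpa)
  ord <- order(agg$dist, agg$C10_S, agg$k1_S)
  agg <- agg[ord, ]
  within <- agg[agg$dist <= halfwidthKpa, , drop = FALSE]
  best <- agg[1, , drop = FALSE]
  rownames(best) <- rownames(within) <- NULL
  list(best = best, withinRange = within,
       outsideRange = nrow(within) == 0L)
}

#' Epithelium / lumen parameter sweep at fixed stromal benchmark values
#'
#' Factorial over the epithelial and lumen neo-Hookean C10 grids with the
#' stroma held at the benchmark HGO parameters (C10 = 17.5 kPa,
#' k1 = 155 kPa by default).
#'
#' @param rves a \linkS4class{PeriodicRVE} or list of them
#' @param C10EGrid epithelial C10 levels (kPa; literature band
#'   0.192-4.801)
#' @param C10AGrid lumen C10 levels (kPa; literature band 1.92-192)
#' @param stromal stromal material (default benchmark HGO)
#' @param nu effective Poisson ratio for the neo-Hookean phases
#' @param coarsen mesh coarsening factor
#' @param ... passed to \code{\link{solveAllCases}}
#' @return data.frame, one row per RVE x combination
#' @export
epitheliumLumenSweep <- function(rves,
                                 C10EGrid = seq(0.192, 4.801,
                                                length.out = 5),
                                 C10AGrid = exp(seq(log(1.92), log(192),
                                                    length.out = 5)),
                                 stromal = NULL, nu = 0.49, coarsen = 1L,
                                 ...) {
  if (is.null(stromal)) stromal <- hgo(17.5, 155, 200, 0, nu = nu)
  grid <- expand.grid(C10_E = C10EGrid, C10_A = C10AGrid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$C10_S <- stromal@C10
  grid$k1_S <- stromal@k1
  prep <- prepModels(rves, coarsen)
  materialsFor <- function(row)
    list(stroma = stromal, epithelium = neoHookean(row$C10_E, nu = nu),
         lumen = neoHookean(row$C10_A, nu = nu))
  sweepCore(prep, materialsFor, grid, ...)
}

#' Linear regression of apparent modulus on constituent area fractions
#'
#' Ordinary least squares of the mean apparent elastic modulus (per RVE) on
#' each constituent's area fraction, mirroring the averaged-over-directions
#' convention. R^2 = 1 - SS_res/SS_tot, defined as 0 for a constant
#' response.
#'
#' @param moduliByRve numeric vector of mean apparent moduli (kPa), or a
#'   list of \linkS4class{ApparentModuli} (then the mean of E11 and E22
#'   over tension and compression is used)
#' @param fractionsByRve n x 3 matrix/data.frame of (stroma, epithelium,
#'   lumen) fractions
#' @return data.frame with one row per constituent: slope, intercept,
#'   r_squared
#' @export
correlateFractions <- function(moduliByRve, fractionsByRve) {
  if (is.list(moduliByRve) && !is.numeric(moduliByRve))
    moduliByRve <- vapply(moduliByRve, function(m)
      mean(c(m@E11t, m@E11c, m@E22t, m@E22c)), numeric(1))
  y <- as.numeric(moduliByRve)
  fr <- as.matrix(fractionsByRve)
  if (length(y) < 3) stop("need at least 3 RVEs for a regression")
  stopifnot(nrow(fr) == length(y), ncol(fr) == 3)
  out <- lapply(1:3, function(k) {
    x <- fr[, k]
    fit <- stats::lm(y ~ x)
    ssTot <- sum((y - mean(y))^2)
    r2 <- if (ssTot <= 0) 0 else {
      ssRes <- sum(stats::residuals(fit)^2)
      1 - ssRes / ssTot
    }
    data.frame(constituent = c("stroma", "epithelium", "lumen")[k],
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2)
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

#' Tension-compression asymmetry indices
#'
#' A_i = (E_iit - E_iic) / E_iic for the two orthotropy directions: the
#' relative excess of the tensile over the compressive secant modulus.
#'
#' @param m an \linkS4class{ApparentModuli}
#' @return named numeric c(A1, A2)
#' @export
asymmetryIndex <- function(m) {
  stopifnot(is(m, "ApparentModuli"))
  if (m@E11c <= 0 || m@E22c <= 0)
    stop("zero or negative compressive modulus: asymmetry undefined")
  c(A1 = (m@E11t - m@E11c) / m@E11c, A2 = (m@E22t - m@E22c) / m@E22c)
}

#' Welch two-sample t-test with significance stars
#'
#' Two-sided unequal-variance t-test; significance classes NS,
#' * (p < .05), ** (p < .01), *** (p < .001). Two identical groups return
#' t = 0, p = 1, NS.
#'
#' @param groupA,groupB numeric vectors with at least 2 values each
#' @return list: t, p, stars
#' @export
welchTTest <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 values")
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0 &&
      mean(groupA) == mean(groupB)) {
    tt <- list(statistic = 0, p.value = 1)
  } else {
    ht <- stats::t.test(groupA, groupB, var.equal = FALSE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  stars <- if (tt$p.value < 0.001) "***" else if (tt$p.value < 0.01) "**"
  else if (tt$p.value < 0.05) "*" else "NS"
  list(t = tt$statistic, p = tt$p.value, stars = stars)
}

#' Write sweep tables and scalar results to disk
#'
#' Tables go to CSV (one file per named table, deterministic column order
#' as given), scalars and metadata to a single JSON file.
#'
#' @param tables named list of data.frames
#' @param results named list of scalars / metadata (e.g. config echo,
#'   seeds)
#' @param path output directory (created if missing)
#' @return invisibly, the JSON path
#' @export
writeReport <- function(tables, results, path) {
  if (!dir.exists(path))
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory ", path)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(path, paste0(nm, ".csv")),
                     row.names = FALSE)
  jp <- file.path(path, "report.json")
  jsonlite::write_json(results, jp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(jp)
}

#' Read a YAML study configuration
#'
#' Expected top-level keys: \code{materials} (per-phase entries with
#' \code{model}: NH or HGO, \code{C10}, and either \code{D1} or \code{nu},
#' plus \code{k1}, \code{k2}, \code{kappa} for HGO), and optional solver
#' settings. Units kPa throughout.
#'
#' @param path YAML file
#' @return list with element \code{materials} (named list of material
#'   objects) and the raw config under \code{raw}
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  mats <- NULL
  if (!is.null(cfg$materials)) {
    mats <- lapply(cfg$materials, function(m) {
      d1 <- m$D1
      nu <- if (is.null(m$nu)) 0.49 else m$nu
      if (identical(toupper(m$model), "HGO"))
        hgo(m$C10, m$k1, if (is.null(m$k2)) 200 else m$k2,
            if (is.null(m$kappa)) 0 else m$kappa, nu = nu, D1 = d1)
      else neoHookean(m$C10, nu = nu, D1 = d1)
    })
  }
  list(materials = mats, raw = cfg)
}
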