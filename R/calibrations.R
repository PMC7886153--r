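# Fossil-calibration prior construction: uniform on [Min, Max], normal
# midpoint priors, and the offset lognormal whose real-space mean above the
# offset is (Max - Min) / 4 with shape solved so the 97.5% quantile hits
# Max.

#' Real-space mean of the offset lognormal calibration prior
#'
#' `M = (max_age - min_age) / 4`, the mean (above the offset) of the
#' lognormal prior placed on a calibrated node with hard minimum `min_age`
#' and soft maximum `max_age` (ages in Mya).
#'
#' @param max_age,min_age node age bounds, `max_age > min_age`.
#' @return M in Mya.
#' @export
lognormal_mean <- function(max_age, min_age) {
  if (any(max_age <= min_age)) {
    stop("parameter error: max_age must exceed min_age", call. = FALSE)
  }
  (max_age - min_age) / 4
}

#' Solve the lognormal shape so the 97.5% quantile equals the maximum age
#'
#' With the prior parameterized by its real-space mean `M = (max - min)/4`
#' above offset `min`, the shape `S` satisfies
#' `min + exp(log M - S^2/2 + z_q S) = max`, i.e. `S^2 - 2 z_q S +
#' 2 log((max-min)/M) = 0`, giving the closed form
#' `S = z_q - sqrt(z_q^2 - 2 log 4)` -- independent of the bounds under the
#' M rule (~0.926 for q = 0.975).
#'
#' @param max_age,min_age node age bounds (any valid pair; S does not
#'   depend on them under the mean rule).
#' @param q the matched quantile (default 0.975).
#' @return the shape parameter S (dimensionless).
#' @export
solve_lognormal_shape <- function(max_age = 2, min_age = 1, q = 0.975) {
  if (any(max_age <= min_age)) {
    stop("parameter error: max_age must exceed min_age", call. = FALSE)
  }
  z <- stats::qnorm(q)
  disc <- z^2 - 2 * log(4)
  if (disc < 0) {
    stop("no real solution: quantile ", q, " is too central to reach the ",
         "maximum with mean (max-min)/4", call. = FALSE)
  }
  z - sqrt(disc)
}

#' Normal calibration from age bounds
#'
#' Midpoint mean with sd chosen so that `[min_age, max_age]` is the central
#' 95% interval: `mean = (max+min)/2`, `sd = (max-min)/(2 z_0.975)`.
#'
#' @param max_age,min_age node age bounds, `max_age > min_age`.
#' @return list with `mean` and `sd` (Mya).
#' @export
normal_calibration <- function(max_age, min_age) {
  if (any(max_age <= min_age)) {
    stop("parameter error: max_age must exceed min_age", call. = FALSE)
  }
  list(mean = (max_age + min_age) / 2,
       sd = (max_age - min_age) / (2 * stats::qnorm(0.975)))
}

#' Construct a calibration point
#'
#' @param name node name.
#' @param mrca_taxa character vector (>= 2) of taxa whose MRCA is
#'   calibrated.
#' @param min_age,max_age age bounds in Mya, `0 < min_age < max_age`.
#' @param kind `"uniform"`, `"offset_lognormal"` or `"normal"`.
#' @param q quantile matched to `max_age` for the lognormal (default
#'   0.975).
#' @return an object of class `calibration_point` with derived parameters:
#'   for the lognormal, `M` (real-space mean above the offset), `S`
#'   (shape), `offset = min_age`; for the normal, `M` (mean) and `sd`.
#' @export
calibration_point <- function(name, mrca_taxa, min_age, max_age,
                              kind = c("uniform", "offset_lognormal",
                                       "normal"),
                              q = 0.975) {
  kind <- match.arg(kind)
  if (!(min_age > 0 && max_age > min_age)) {
    stop("parameter error: need 0 < min_age < max_age (", name, ")",
         call. = FALSE)
  }
  cp <- list(name = name, mrca_taxa = mrca_taxa, min_age = min_age,
             max_age = max_age, kind = kind, M = NA_real_, S = NA_real_,
             sd = NA_real_, offset = NA_real_, q = q)
  if (kind == "offset_lognormal") {
    cp$M <- lognormal_mean(max_age, min_age)
    cp$S <- solve_lognormal_shape(max_age, min_age, q)
    cp$offset <- min_age
  } else if (kind == "normal") {
    nc <- normal_calibration(max_age, min_age)
    cp$M <- nc$mean
    cp$sd <- nc$sd
  }
  structure(cp, class = "calibration_point")
}

#' @export
print.calibration_point <- function(x, ...) {
  cat(x$name, ": ", x$kind, " [", x$min_age, ", ", x$max_age, "] Mya",
      sep = "")
  if (x$kind == "offset_lognormal") {
    cat(sprintf("; offset=%g, M=%g, S=%.3f", x$offset, x$M, x$S))
  } else if (x$kind == "normal") {
    cat(sprintf("; mean=%g, sd=%.4f", x$M, x$sd))
  }
  cat("\n")
  invisible(x)
}

# lognormal log-scale parameters from real-space mean M and shape S
lnorm_pars <- function(cp) {
  list(meanlog = log(cp$M) - cp$S^2 / 2, sdlog = cp$S)
}

#' Prior density of a calibration point
#'
#' @param cp a `calibration_point`.
#' @param t age(s) in Mya.
#' @return density values (0 below the offset for the lognormal).
#' @export
prior_density <- function(cp, t) {
  switch(cp$kind,
    uniform = stats::dunif(t, cp$min_age, cp$max_age),
    normal = stats::dnorm(t, cp$M, cp$sd),
    offset_lognormal = {
      p <- lnorm_pars(cp)
      ifelse(t <= cp$offset, 0,
             stats::dlnorm(t - cp$offset, p$meanlog, p$sdlog))
    })
}

#' Prior quantile of a calibration point
#'
#' Inverse of the prior's cumulative distribution; for the offset
#' lognormal built by [calibration_point()], `prior_quantile(cp, 0.975)`
#' equals `max_age`.
#'
#' @param cp a `calibration_point`.
#' @param p probability / probabilities.
#' @return ages in Mya.
#' @export
prior_quantile <- function(cp, p) {
  switch(cp$kind,
    uniform = stats::qunif(p, cp$min_age, cp$max_age),
    normal = stats::qnorm(p, cp$M, cp$sd),
    offset_lognormal = {
      pr <- lnorm_pars(cp)
      cp$offset + stats::qlnorm(p, pr$meanlog, pr$sdlog)
    })
}

#' Load a calibration sheet
#'
#' Reads a TSV with columns `name`, `taxa` (comma-separated MRCA taxa),
#' `max`, `distribution` (`U`, `L` or `N`), `min`. U/L rows are realized as
#' uniform or offset-lognormal priors according to `strategy`; `N` rows are
#' always normal.
#'
#' @param path TSV path.
#' @param strategy `"U"` (uniform) or `"L"` (offset lognormal) for the U/L
#'   rows.
#' @return list of `calibration_point`s.
#' @export
load_calibration_sheet <- function(path, strategy = c("L", "U")) {
  strategy <- match.arg(strategy)
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "taxa", "max", "distribution", "min")
  missing <- setdiff(needed, names(sheet))
  if (length(missing)) {
    stop("calibration sheet missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- vector("list", nrow(sheet))
  for (r in seq_len(nrow(sheet))) {
    row <- sheet[r, ]
    kind <- switch(toupper(trimws(row$distribution)),
      N = "normal",
      `U/L` = , UL = , U = , L = if (strategy == "L") "offset_lognormal"
                                 else "uniform",
      stop("row ", r + 1L, ": unknown distribution '", row$distribution,
           "'", call. = FALSE))
    cp <- tryCatch(
      calibration_point(row$name,
                        trimws(strsplit(row$taxa, ",")[[1L]]),
                        min_age = as.numeric(row$min),
                        max_age = as.numeric(row$max), kind = kind),
      error = function(e) stop("row ", r + 1L, " (", row$name, "): ",
                               conditionMessage(e), call. = FALSE))
    out[[r]] <- cp
  }
  out
}

#' Export calibration priors
#'
#' Writes a TSV of the derived prior parameters and, optionally, XML prior
#' fragments (offset / real-space mean / shape fields) usable in Bayesian
#' dating configuration files.
#'
#' @param points list of `calibration_point`s.
#' @param path output TSV path.
#' @param xml_path optional output path for the XML fragments.
#' @return the prior table, invisibly.
#' @export
export_priors <- function(points, path, xml_path = NULL) {
  tab <- do.call(rbind, lapply(points, function(cp) {
    data.frame(name = cp$name, taxa = paste(cp$mrca_taxa, collapse = ","),
               kind = cp$kind, min = cp$min_age, max = cp$max_age,
               M = cp$M, S = cp$S, sd = cp$sd, offset = cp$offset,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(xml_path)) {
    frag <- unlist(lapply(points, function(cp) {
      switch(cp$kind,
        uniform = sprintf(
          '<distr spec="Uniform" id="%s" lower="%g" upper="%g"/>',
          cp$name, cp$min_age, cp$max_age),
        normal = sprintf(
          '<distr spec="Normal" id="%s" mean="%g" sigma="%g"/>',
          cp$name, cp$M, cp$sd),
        offset_lognormal = sprintf(
          paste0('<distr spec="LogNormalDistributionModel" id="%s" ',
                 'M="%g" S="%g" meanInRealSpace="true" offset="%g"/>'),
          cp$name, cp$M, cp$S, cp$offset))
    }))
    writeLines(frag, xml_path)
  }
  invisible(tab)
}
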