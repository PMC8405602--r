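#' Per-group summary statistics of range areas
#'
#' Sample statistics (n, mean, median, sd with the n-1 denominator, min,
#' max) of home-range or core areas per group. Groups with a single value
#' report `sd = 0` and are flagged in the `degenerate` column.
#'
#' @param values numeric vector of areas (km^2).
#' @param groups optional grouping labels (same length); a single `"all"`
#'   group when omitted.
#' @return data.frame with one row per group.
#' @export
rangeStats <- function(values, groups = NULL) {
  if (!length(values)) stop("no values supplied")
  if (is.null(groups)) groups <- rep("all", length(values))
  stopifnot(length(groups) == length(values))
  if (anyNA(values)) stop("values must not contain NA")
  rows <- lapply(split(values, groups), function(v) {
    data.frame(n = length(v), mean = mean(v), median = median(v),
               sd = if (length(v) > 1) sd(v) else 0,
               min = min(v), max = max(v), degenerate = length(v) == 1)
  })
  out <- do.call(rbind, rows)
  out <- cbind(group = names(rows), out)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Fisher's LSD post-hoc
#'
#' Tests for differences in mean range size among groups. The omnibus F
#' and p come from the standard one-way analysis of variance on the raw
#' km^2 values (pass `logTransform = TRUE` to analyse log areas instead);
#' pairwise comparisons use Fisher's least significant difference: a
#' two-sample t statistic with the pooled within-group mean square and its
#' degrees of freedom, unadjusted for multiplicity.
#'
#' @param values numeric response (km^2 areas).
#' @param groups grouping labels, at least two groups.
#' @param logTransform analyse `log(values)` (default `FALSE`).
#' @return an [AnovaResult-class].
#' @export
rangeAnova <- function(values, groups, logTransform = FALSE) {
  stopifnot(length(groups) == length(values))
  if (anyNA(values)) stop("values must not contain NA")
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least two groups")
  if (length(values) <= nlevels(g))
    stop("need more observations than groups")
  y <- if (logTransform) log(values) else values
  note <- ""
  dfb <- nlevels(g) - 1L
  dfw <- length(y) - nlevels(g)
  ssw <- sum(unlist(tapply(y, g, function(x) (x - mean(x))^2)))
  msw <- ssw / dfw
  if (msw <= .Machine$double.eps * max(mean(y)^2, 1)) {
    ## zero within-group variance: F is 0/0 when the means also coincide
    gm <- tapply(y, g, mean)
    if (max(gm) - min(gm) < 1e-12) {
      note <- "degenerate: zero variance within and between groups; F set to 0"
      Fv <- 0; pv <- 1
    } else {
      Fv <- Inf; pv <- 0
      note <- "zero within-group variance with distinct means"
    }
  } else {
    av <- anova(lm(y ~ g))
    msw <- av["Residuals", "Mean Sq"]
    Fv <- av["g", "F value"]
    pv <- av["g", "Pr(>F)"]
  }
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  prs <- utils::combn(levels(g), 2)
  posthoc <- data.frame(group_a = prs[1, ], group_b = prs[2, ])
  posthoc$diff <- means[posthoc$group_a] - means[posthoc$group_b]
  se <- sqrt(msw * (1 / ns[posthoc$group_a] + 1 / ns[posthoc$group_b]))
  posthoc$t <- as.numeric(posthoc$diff / se)
  posthoc$p <- 2 * pt(-abs(posthoc$t), dfw)
  posthoc$diff <- as.numeric(posthoc$diff)
  rownames(posthoc) <- NULL
  new("AnovaResult", F = as.numeric(Fv), dfBetween = as.integer(dfb),
      dfWithin = as.integer(dfw), p = as.numeric(pv), posthoc = posthoc,
      note = note)
}

#' Seasonal range summary table
#'
#' Summarises per-bird-season range areas into the conventional seasonal
#' table: one row per season with n, mean, median, sd, min, max for each
#' measure present (`core50_km2` and/or `homerange95_km2`).
#'
#' @param seasonal data.frame with a `season` column plus one or both of
#'   `core50_km2`, `homerange95_km2`; e.g. from [readSeasonalRanges()] or
#'   the pipeline's per-season output.
#' @return data.frame, one row per season and measure.
#' @export
seasonalRangeStats <- function(seasonal) {
  stopifnot("season" %in% names(seasonal))
  meas <- intersect(c("core50_km2", "homerange95_km2"), names(seasonal))
  if (!length(meas)) stop("no area columns found")
  out <- NULL
  for (m in meas) {
    ok <- !is.na(seasonal[[m]])
    st <- rangeStats(seasonal[[m]][ok], seasonal$season[ok])
    st <- cbind(measure = m, st)
    names(st)[names(st) == "group"] <- "season"
    out <- rbind(out, st)
  }
  sOrd <- c("spring", "summer", "autumn", "winter")
  out$season <- as.character(out$season)
  out <- out[order(match(out$measure, meas),
                   match(out$season, sOrd, nomatch = 99)), ]
  rownames(out) <- NULL
  out
}

#' Read a per-bird seasonal home-range file
#'
#' Reads a CSV of per-bird, per-season range areas (columns mappable to
#' bird id, season, and the 50%/95% areas in km^2), the layout used for
#' deposited seasonal home-range tables.
#'
#' @param path CSV path.
#' @param cols named list mapping `bird`, `season`, `core50`, `hr95` to
#'   column names in the file.
#' @return data.frame with `bird_id`, `season`, `core50_km2`,
#'   `homerange95_km2`.
#' @export
readSeasonalRanges <- function(path,
                               cols = list(bird = "bird_id",
                                           season = "season",
                                           core50 = "core50_km2",
                                           hr95 = "homerange95_km2")) {
  if (!file.exists(path)) stop("seasonal range file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(unlist(cols), names(raw))
  if (length(miss))
    stop("seasonal file lacks column(s): ", paste(miss, collapse = ", "))
  data.frame(bird_id = as.character(raw[[cols$bird]]),
             season = tolower(raw[[cols$season]]),
             core50_km2 = as.numeric(raw[[cols$core50]]),
             homerange95_km2 = as.numeric(raw[[cols$hr95]]))
}
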