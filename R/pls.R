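# Partial least squares phase delineation: daily chill (CP/day) and heat
# (GDH/day) accumulation rates are regressed on bloom dates across seasons;
# runs of negative, VIP-significant model coefficients delimit the chilling
# and forcing phases, and the last day of the chilling phase is the
# endodormancy-break date.

#' NIPALS partial least squares regression (single response)
#'
#' Fits a PLS1 model by the NIPALS algorithm on centred and scaled
#' predictors and a centred response, and computes variable importance in
#' projection (VIP) scores by the standard formula (per-component explained
#' response variance weighted squared normalised weights). Columns with zero
#' variance are excluded from the fit and reported with coefficient 0 and
#' VIP 0. A constant response yields all-zero coefficients.
#'
#' @param X Numeric matrix, seasons x predictors (e.g. daily accumulation
#'   rates; column names are kept and used as the day grid downstream).
#' @param y Numeric response (bloom day-of-season per season).
#' @param n_components Number of latent components (default 2); must not
#'   exceed the rank of the scaled predictor matrix.
#' @return An object of class `pls_fit`: list with `coefficients` and `vip`
#'   (full-length, named as `colnames(X)`), `weights`, `loadings`, `scores`,
#'   `q`, `ncomp_used`, `x_mean`, `x_sd`, `y_mean`.
#' @export
pls_fit <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 3)
  p_all <- ncol(X)
  cn <- colnames(X)
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, sd)
  keep <- which(x_sd > 0)
  coefs <- setNames(numeric(p_all), cn)
  vip <- setNames(numeric(p_all), cn)
  empty <- structure(
    list(coefficients = coefs, vip = vip, weights = NULL, loadings = NULL,
         scores = NULL, q = numeric(0), ncomp_used = 0L,
         x_mean = x_mean, x_sd = x_sd, y_mean = mean(y)),
    class = "pls_fit")
  if (!length(keep) || sd(y) == 0) return(empty)
  Xs <- scale(X[, keep, drop = FALSE], center = TRUE, scale = TRUE)
  rk <- qr(Xs)$rank
  if (n_components > rk) {
    stop("n_components (", n_components, ") exceeds predictor rank (", rk, ")")
  }
  y0 <- y - mean(y)
  n <- nrow(Xs); p <- length(keep)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  qv <- numeric(n_components)
  ssy <- numeric(n_components)     # q_a^2 * t_a't_a: response variance per comp
  Xd <- Xs; yd <- y0
  a_used <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    pa <- crossprod(Xd, t_) / tt
    qa <- sum(yd * t_) / tt
    Xd <- Xd - t_ %*% t(pa)
    yd <- yd - qa * t_
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- t_
    qv[a] <- qa; ssy[a] <- qa^2 * tt
    a_used <- a
  }
  if (a_used == 0L) return(empty)
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  qv <- qv[seq_len(a_used)]; ssy <- ssy[seq_len(a_used)]
  B <- W %*% solve(crossprod(P, W), qv)          # coefficients on scaled data
  coefs[keep] <- as.numeric(B)
  vip[keep] <- sqrt(p * as.numeric(W^2 %*% ssy) / sum(ssy))
  structure(
    list(coefficients = coefs, vip = vip, weights = W, loadings = P,
         scores = Tm, q = qv, ncomp_used = a_used,
         x_mean = x_mean, x_sd = x_sd, y_mean = mean(y)),
    class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit: %d component(s), %d predictors (%d informative)>\n",
              x$ncomp_used, length(x$coefficients), sum(x$vip > 0)))
  invisible(x)
}

#' Centred running mean
#'
#' Running mean over a centred window truncated at the edges; applied to
#' daily accumulation rates before PLS to stabilise day-to-day noise.
#'
#' @param x Numeric vector.
#' @param k Odd window length (k = 1 returns `x`).
#' @return Smoothed vector of the same length.
#' @export
running_mean <- function(x, k = 11) {
  stopifnot(k %% 2 == 1, k >= 1)
  if (k == 1) return(x)
  half <- (k - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) mean(x[max(1, i - half):min(n, i + half)]),
         numeric(1))
}

#' Daily chill or heat accumulation matrix
#'
#' Builds the seasons x days predictor matrix for PLS phase delineation:
#' each cell is the amount of chill (Dynamic CP) or heat (GDH) accumulated
#' on that day of the season. Columns are aligned on the day-of-season
#' index (October 1 = 1; September days carry indices <= 0) and restricted
#' to the indices common to all seasons.
#'
#' @param weather_seasons Named list of per-season [temperature_series()]
#'   (names are season labels such as `"2016-2017"`), each covering
#'   September 1 through April 30.
#' @param model `"dynamic"` (CP/day) or `"gdh"` (GDH/day).
#' @return Numeric matrix with seasons as rows (named by label) and day
#'   indices as columns (named by index).
#' @export
daily_accumulation_matrix <- function(weather_seasons, model = c("dynamic", "gdh")) {
  model <- match.arg(model)
  stopifnot(is.list(weather_seasons), length(names(weather_seasons)) > 0)
  rows <- lapply(names(weather_seasons), function(sl) {
    s <- season(sl)
    ser <- weather_seasons[[sl]]
    cs <- switch(model,
                 dynamic = dynamic_chill_portions(ser),
                 gdh = growing_degree_hours(ser))
    day <- as.Date(format(cs$timestamp, "%Y-%m-%d", tz = "UTC"))
    agg <- aggregate(cs$contribution, by = list(date = day), FUN = sum)
    setNames(agg$x, day_of_season(agg$date, s))
  })
  common <- Reduce(intersect, lapply(rows, names))
  common <- common[order(as.integer(common))]
  M <- t(vapply(rows, function(r) r[common], numeric(length(common))))
  rownames(M) <- names(weather_seasons)
  colnames(M) <- common
  M
}

# longest run of qualifying day indices, allowing internal gaps of at most
# `gap` non-qualifying days; ties broken by the later run
find_phase_run <- function(days, gap) {
  if (!length(days)) return(NULL)
  days <- sort(days)
  grp <- cumsum(c(1, diff(days) > gap + 1))
  spans <- vapply(split(days, grp), function(d) d[length(d)] - d[1] + 1, numeric(1))
  best <- max(which(spans == max(spans)))
  d <- split(days, grp)[[best]]
  c(start = d[1], end = d[length(d)])
}

#' Chilling and forcing phases from PLS fits
#'
#' Days on which a higher daily accumulation rate advances bloom show
#' negative model coefficients with VIP above the significance threshold.
#' The chilling phase is the longest such run (allowing short internal gaps)
#' in the chill-rate model; its last day is the endodormancy-break date.
#' The forcing phase is delineated likewise from the heat-rate model among
#' runs starting after the chilling phase ends; the transition is the gap
#' between the two phases.
#'
#' @param chill_fit A [pls_fit()] on the daily CP matrix.
#' @param heat_fit A [pls_fit()] on the daily GDH matrix.
#' @param vip_threshold VIP significance threshold (default 0.8).
#' @param gap_days Maximum run of non-qualifying days tolerated inside a
#'   phase (default 5).
#' @return A list: `status`, `chilling_phase` and `forcing_phase`
#'   (`c(start, end)` day indices, `NA` when undetermined),
#'   `transition_days`, and `break_day` (the chilling phase end).
#' @export
pls_phase_delineation <- function(chill_fit, heat_fit, vip_threshold = 0.8,
                                  gap_days = 5) {
  stopifnot(inherits(chill_fit, "pls_fit"), inherits(heat_fit, "pls_fit"))
  qual_days <- function(fit) {
    idx <- as.integer(names(fit$coefficients))
    idx[fit$coefficients < 0 & fit$vip > vip_threshold]
  }
  chill <- find_phase_run(qual_days(chill_fit), gap_days)
  if (is.null(chill)) {
    return(list(status = "undetermined",
                chilling_phase = c(NA_integer_, NA_integer_),
                forcing_phase = c(NA_integer_, NA_integer_),
                transition_days = NA_integer_, break_day = NA_integer_))
  }
  hq <- qual_days(heat_fit)
  forcing <- find_phase_run(hq[hq > chill[["end"]]], gap_days)
  if (is.null(forcing)) {
    return(list(status = "no_forcing_phase",
                chilling_phase = unname(chill),
                forcing_phase = c(NA_integer_, NA_integer_),
                transition_days = NA_integer_,
                break_day = as.integer(chill[["end"]])))
  }
  list(status = "ok",
       chilling_phase = unname(chill),
       forcing_phase = unname(forcing),
       transition_days = max(0L, as.integer(forcing[["start"]] - chill[["end"]] - 1)),
       break_day = as.integer(chill[["end"]]))
}

#' Correlation-method break date from weather and blooms
#'
#' Convenience wrapper chaining [daily_mean()], [correlation_profile()] and
#' [correlation_break_date()] for one cultivar.
#'
#' @inheritParams daily_accumulation_matrix
#' @param blooms Data frame `season`, `f50_date` for one cultivar.
#' @param window_days,alpha,min_years Passed to [correlation_profile()].
#' @return The [correlation_break_date()] result, plus `profile`.
#' @export
estimate_break_correlation <- function(weather_seasons, blooms,
                                       window_days = 15, alpha = 0.05,
                                       min_years = 11) {
  dm <- do.call(rbind, lapply(names(weather_seasons), function(sl) {
    d <- daily_mean(weather_seasons[[sl]])
    d$season <- sl
    d
  }))
  prof <- correlation_profile(dm, blooms, window_days = window_days,
                              alpha = alpha, min_years = min_years)
  res <- correlation_break_date(prof)
  res$profile <- prof
  res
}

#' PLS-method break date from weather and blooms
#'
#' Convenience wrapper: builds the daily CP and GDH matrices, smooths them
#' with a centred running mean, fits NIPALS PLS to the bloom day-of-season,
#' and delineates the chilling and forcing phases.
#'
#' @inheritParams daily_accumulation_matrix
#' @param blooms Data frame `season`, `f50_date` for one cultivar.
#' @param n_components Latent components (default 2).
#' @param vip_threshold,gap_days Passed to [pls_phase_delineation()].
#' @param smooth_days Running-mean window on daily rates (default 11; 1
#'   disables smoothing).
#' @return The [pls_phase_delineation()] result, plus `chill_fit` and
#'   `heat_fit`.
#' @export
estimate_break_pls <- function(weather_seasons, blooms, n_components = 2,
                               vip_threshold = 0.8, gap_days = 5,
                               smooth_days = 11) {
  Xc <- daily_accumulation_matrix(weather_seasons, "dynamic")
  Xh <- daily_accumulation_matrix(weather_seasons, "gdh")
  if (smooth_days > 1) {
    cn <- colnames(Xc); rn <- rownames(Xc)
    Xc <- t(apply(Xc, 1, running_mean, k = smooth_days))
    Xh <- t(apply(Xh, 1, running_mean, k = smooth_days))
    dimnames(Xc) <- dimnames(Xh) <- list(rn, cn)
  }
  labs <- rownames(Xc)
  y <- vapply(labs, function(sl) {
    f50 <- blooms$f50_date[blooms$season == sl]
    if (!length(f50)) return(NA_real_)
    as.numeric(day_of_season(f50[1], season(sl)))
  }, numeric(1))
  keep <- !is.na(y)
  if (sum(keep) < length(labs)) {
    warning("dropping season(s) without bloom record: ",
            paste(labs[!keep], collapse = ", "))
  }
  chill_fit <- pls_fit(Xc[keep, , drop = FALSE], y[keep], n_components)
  heat_fit <- pls_fit(Xh[keep, , drop = FALSE], y[keep], n_components)
  res <- pls_phase_delineation(chill_fit, heat_fit, vip_threshold, gap_days)
  res$chill_fit <- chill_fit
  res$heat_fit <- heat_fit
  res
}
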