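# Behavioral scoring (open field, object recognition), group statistics with
# normality routing, cohort accounting and inter-rater reliability.

#' Score an open-field session from a position/event log
#'
#' The arena is a `grid x grid` square grid (6 x 6 by default) whose central
#' 2 x 2 squares form the internal area; everything else is peripheral
#' (external). The log is a data frame with columns `time` (s, ascending,
#' within the session), `x`, `y` (grid squares, 1-based) and optionally
#' `event` (`"position"`, `"grooming"`, `"rearing"`); rows without an event
#' column are positions. Latency is the time of the first position outside
#' the starting square (the session length if the animal never leaves);
#' square crossings are counted at every grid-cell change and classified by
#' the destination square; dwell time is attributed to the occupied square
#' until the next sample (then to session end); velocity is total squares
#' crossed per second of moving (exploring) time.
#'
#' @param log Event log data frame.
#' @param session Session length in seconds (default 600).
#' @param grid Squares per side (default 6).
#' @return Object of class `open_field_record` with `latency`,
#'   `external_squares`, `internal_squares`, `total_squares`,
#'   `time_external`, `time_internal`, `total_time_exploring`, `velocity`,
#'   `grooming`, `rearing`.
#' @export
score_open_field <- function(log, session = 600, grid = 6) {
  if (!all(c("time", "x", "y") %in% names(log)))
    stop("log needs columns time, x, y")
  if (is.null(log$event)) log$event <- "position"
  if (any(log$time < 0 | log$time > session))
    stop("timestamps must lie within the session (0-", session, " s)")
  pos <- log[log$event == "position", , drop = FALSE]
  pos <- pos[order(pos$time), , drop = FALSE]
  if (nrow(pos) == 0) stop("log contains no positions")
  if (any(pos$x < 1 | pos$x > grid | pos$y < 1 | pos$y > grid))
    stop("positions off-grid: x and y must lie in 1..", grid)
  lo <- grid / 2; hi <- grid / 2 + 1
  internal <- function(x, y) x >= lo & x <= hi & y >= lo & y <= hi
  cell <- paste(pos$x, pos$y)
  start_cell <- cell[1]
  moved <- which(cell != start_cell)
  latency <- if (length(moved) == 0) session else pos$time[moved[1]]
  changed <- c(FALSE, cell[-1] != cell[-nrow(pos)])
  dest_internal <- internal(pos$x, pos$y)
  ext_cross <- sum(changed & !dest_internal)
  int_cross <- sum(changed & dest_internal)
  dwell <- diff(c(pos$time, session))
  time_int <- sum(dwell[dest_internal])
  time_ext <- sum(dwell[!dest_internal])
  # moving time: dwell intervals that end in a crossing
  ends_in_cross <- c(changed[-1], FALSE)
  t_explore <- sum(dwell[ends_in_cross])
  total <- ext_cross + int_cross
  structure(list(latency = latency, external_squares = ext_cross,
                 internal_squares = int_cross, total_squares = total,
                 time_external = time_ext, time_internal = time_int,
                 total_time_exploring = t_explore,
                 velocity = if (t_explore > 0) total / t_explore else 0,
                 grooming = sum(log$event == "grooming"),
                 rearing = sum(log$event == "rearing"),
                 session = session),
            class = "open_field_record")
}

#' Score an object-recognition task
#'
#' The familiarization phase presents two identical objects (left/right); in
#' the testing phase one is replaced by a novel object. The discrimination
#' index is `DI = (novel - familiar) / (novel + familiar)` on cumulative
#' exploration times, and the learning criterion is `DI > 0` (strictly).
#' Animals that explored neither object during familiarization, or never
#' explored the familiar object during testing, are flagged excluded with a
#' reason; DI is missing when the testing exploration total is zero.
#'
#' @param familiarization Data frame of exploration bouts: columns `object`
#'   (`"left"`/`"right"`) and `duration` (s).
#' @param testing Data frame: columns `object` (`"novel"`/`"familiar"`) and
#'   `duration` (s).
#' @return Object of class `recognition_record` with `fam_left`,
#'   `fam_right`, `novel`, `familiar`, `di`, `learned`, `excluded`,
#'   `exclusion_reason`.
#' @export
score_recognition <- function(familiarization, testing) {
  tot <- function(df, obj) sum(df$duration[df$object == obj])
  fl <- tot(familiarization, "left")
  fr <- tot(familiarization, "right")
  nv <- tot(testing, "novel")
  fm <- tot(testing, "familiar")
  excluded <- FALSE
  reason <- NA_character_
  if (fl + fr == 0) {
    excluded <- TRUE
    reason <- "no object explored in familiarization phase"
  } else if (fm == 0) {
    excluded <- TRUE
    reason <- "familiar object not explored in testing phase"
  }
  di <- if (nv + fm > 0) (nv - fm) / (nv + fm) else NA_real_
  structure(list(fam_left = fl, fam_right = fr, novel = nv, familiar = fm,
                 di = di, learned = isTRUE(di > 0), excluded = excluded,
                 exclusion_reason = reason),
            class = "recognition_record")
}

#' Group comparison with normality routing
#'
#' Quantitative variables are routed by per-group Shapiro-Wilk tests (alpha
#' 0.05): normal variables are summarized as mean (SD) and compared with a
#' gender-adjusted linear model on raw values; non-normal variables as
#' median (IQR) with the same model on `log(x + offset)` (offset 1 when the
#' variable contains zeros, 0 otherwise). Categorical variables use an
#' uncorrected chi-squared test on the contingency table. The reported p is
#' for the group term.
#'
#' @param table Study table data frame with columns `group` (levels
#'   `control`, `case`), `gender`, and the variable.
#' @param variable Column name to compare.
#' @param kind `"quantitative"` or `"categorical"`.
#' @param alpha_normal Shapiro-Wilk routing threshold (default 0.05).
#' @return Object of class `group_comparison` with `variable`, `kind`,
#'   `normal`, `summaries` (named character per group), `p`, `method`,
#'   `statistic`.
#' @export
compare_groups <- function(table, variable, kind = c("quantitative",
                                                     "categorical"),
                           alpha_normal = 0.05) {
  kind <- match.arg(kind)
  if (!variable %in% names(table)) stop("variable '", variable, "' not found")
  group <- factor(table$group, levels = c("control", "case"))
  x <- table[[variable]]
  if (kind == "categorical") {
    tab <- base::table(group, factor(x))
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    summ <- apply(tab, 1, function(r)
      paste0(paste(r, collapse = "/"), " (",
             paste(sprintf("%.1f%%", 100 * r / sum(r)), collapse = "/"), ")"))
    return(structure(list(variable = variable, kind = kind, normal = NA,
                          summaries = summ, p = unname(ct$p.value),
                          statistic = unname(ct$statistic),
                          method = "chi-squared (uncorrected)"),
                     class = "group_comparison"))
  }
  ok <- is.finite(x)
  x <- x[ok]; group2 <- droplevels(group[ok])
  gender <- factor(table$gender)[ok]
  if (any(base::table(group2) < 3)) stop("need at least 3 subjects per group")
  swp <- vapply(split(x, group2), function(v) {
    if (length(unique(v)) < 3) return(0) # degenerate: route non-normal
    shapiro.test(v)$p.value
  }, numeric(1))
  normal <- all(swp > alpha_normal)
  if (normal) {
    y <- x
    summ <- vapply(split(x, group2), function(v)
      sprintf("%.1f (%.1f)", mean(v), sd(v)), character(1))
    method <- "gender-adjusted linear model"
  } else {
    # offset 1 for zero-valued variables; negative-valued variables are
    # shifted so the minimum maps to 1 before the log
    offset <- if (min(x) > 0) 0 else if (min(x) == 0) 1 else 1 - min(x)
    y <- log(x + offset)
    summ <- vapply(split(x, group2), function(v)
      sprintf("%.1f (%.1f)", median(v), stats::IQR(v)), character(1))
    method <- "gender-adjusted linear model on log-transformed values"
  }
  X <- model.matrix(~ group2 + gender)
  if (qr(X)$rank < ncol(X)) {
    warning("gender is confounded with group; covariate dropped")
    fit <- lm(y ~ group2)
    method <- sub("gender-adjusted ", "", method)
  } else fit <- lm(y ~ group2 + gender)
  co <- summary(fit)$coefficients
  row <- grep("^group2", rownames(co))
  structure(list(variable = variable, kind = kind, normal = normal,
                 summaries = summ, p = unname(co[row, 4]),
                 statistic = unname(co[row, 3]), method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  marker <- if (isTRUE(!x$normal)) " †" else ""
  cat(x$variable, marker, ": ",
      paste(names(x$summaries), x$summaries, sep = " = ", collapse = "; "),
      ", p = ", signif(x$p, 3), " [", x$method, "]\n", sep = "")
  invisible(x)
}

#' Summary table of group comparisons
#'
#' One row per variable: per-group summary (mean (SD) for normal variables,
#' median (IQR), marked with a dagger, otherwise) and the gender-adjusted p.
#'
#' @param table Study table.
#' @param variables Character vector of quantitative column names.
#' @return Data frame with columns `variable`, `control`, `case`, `p`,
#'   `normal`.
#' @export
report_group_table <- function(table, variables) {
  rows <- lapply(variables, function(v) {
    cg <- compare_groups(table, v)
    data.frame(variable = paste0(v, if (!cg$normal) " †" else ""),
               control = cg$summaries[["control"]],
               case = cg$summaries[["case"]],
               p = round(cg$p, 3), normal = cg$normal,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort flow accounting
#'
#' From per-group flow counts (included at induction, alive at delivery,
#' survived the first week, functionally evaluated, excluded after imaging)
#' computes stillbirth rate `(included - alive)/included`, neonatal mortality
#' `(alive - survived)/alive` (percentages to one decimal) and the final
#' sample `evaluated - excluded`.
#'
#' @param flow Data frame with one row per group (rownames or a `group`
#'   column) and columns `included`, `alive`, `survived`, `evaluated`,
#'   `excluded`.
#' @return Data frame with per-group rates and final sample sizes; attribute
#'   `final_total` holds the overall final sample.
#' @export
cohort_accounting <- function(flow) {
  need <- c("included", "alive", "survived", "evaluated", "excluded")
  if (!all(need %in% names(flow)))
    stop("flow needs columns: ", paste(need, collapse = ", "))
  with(flow, {
    if (any(alive > included | survived > alive | evaluated > survived))
      stop("flow counts must be monotone non-increasing")
    if (any(excluded > evaluated)) stop("excluded cannot exceed evaluated")
  })
  out <- data.frame(
    group = if (!is.null(flow$group)) flow$group else rownames(flow),
    stillbirth_pct = round(100 * (flow$included - flow$alive) / flow$included, 1),
    neonatal_mortality_pct = round(100 * (flow$alive - flow$survived) / flow$alive, 1),
    final_n = flow$evaluated - flow$excluded,
    stringsAsFactors = FALSE)
  attr(out, "final_total") <- sum(out$final_n)
  out
}

#' Intraclass correlation between two observers
#'
#' Single-measure two-way mixed-model ICC; `type = "agreement"` (default)
#' penalizes systematic observer offsets, `type = "consistency"` does not.
#'
#' @param x,y Paired score vectors from the two observers (n >= 3).
#' @param type `"agreement"` or `"consistency"`.
#' @return ICC value.
#' @export
interrater_icc <- function(x, y, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  if (length(x) != length(y)) stop("score vectors must be paired")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired scores")
  m <- cbind(x, y)
  k <- 2
  gm <- mean(m)
  if (var(as.vector(m)) == 0) stop("zero total variance: ICC undefined")
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  ssr <- k * sum((rowm - gm)^2)
  ssc <- n * sum((colm - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "agreement")
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  else
    (msr - mse) / (msr + (k - 1) * mse)
}
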