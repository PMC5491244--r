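#' Run the phantom cohort study
#'
#' Reproduces the experimental design of the feasibility analysis: a cohort
#' of seeded phantoms, each planned with every requested field arrangement
#' (the full phantom -> trace -> balance -> normalize -> evaluate pipeline),
#' yielding one metrics row per (phantom, plan type).  Per-field traces are
#' shared across plan types of the same phantom.  Deterministic given
#' `base_seed`.
#'
#' @param n_phantoms cohort size (>= 2; default 12).
#' @param base_seed integer; phantom i uses seed `base_seed + i`.
#' @param plan_types character subset of `"1F"`, `"2F"`, `"3F"`, `"4F"`.
#' @param params a [phantom_params()] template (its seed is overridden).
#' @param bm a [beam_model_params()].
#' @param rb a [radiobiology_params()].
#' @param rx_dose,coverage,tolerance planning parameters.
#' @param depth_angles beam angles (degrees) at which the deepest CTV depth
#'   is recorded per phantom.
#' @return list with `metrics` (data.frame, one row per phantom x plan) and
#'   `depths` (data.frame, one row per phantom x angle).
#' @export
run_cohort <- function(n_phantoms = 12, base_seed = 1,
                       plan_types = c("2F", "3F", "4F"),
                       params = phantom_params(),
                       bm = default_beam_model(),
                       rb = radiobiology_params(),
                       rx_dose = 20, coverage = 0.8, tolerance = 0.10,
                       depth_angles = c(0, 60, 90, 180, 270, 300)) {
  stopifnot(n_phantoms >= 2,
            all(plan_types %in% c("1F", "2F", "3F", "4F")))
  n_fields <- as.integer(substr(plan_types, 1, 1))
  metrics <- list()
  depths <- list()
  for (i in seq_len(n_phantoms)) {
    params$seed <- base_seed + i
    ph <- tryCatch(generate_head_phantom(params), error = function(e)
      stop("phantom ", i, " (stage: phantom): ", conditionMessage(e)))
    st <- ph$structures
    depths[[i]] <- data.frame(
      phantom = i, angle = depth_angles,
      depth_cm = vapply(depth_angles, function(a)
        max_tumor_depth(st$masks$body, st$masks$CTV, a, st$geom),
        numeric(1)))
    # trace each distinct angle once, reuse across plan types
    angles <- sort(unique(unlist(lapply(n_fields, function(k)
      vapply(standard_field_set(k), `[[`, numeric(1), "angle")))))
    boron <- build_boron_map(st, rb, bm$reference_boron_ppm)
    rate_maps <- lapply(angles, function(a)
      tryCatch(field_rbe_rate(ph$materials, st, beam_spec(a), bm, rb, boron),
               error = function(e) stop("phantom ", i, " (stage: trace ",
                                        a, " deg): ", conditionMessage(e))))
    names(rate_maps) <- as.character(angles)
    for (j in seq_along(plan_types)) {
      plan <- tryCatch(
        plan_treatment(ph, standard_field_set(n_fields[j]), bm, rb,
                       rx_dose, coverage, tolerance,
                       field_rate_maps = rate_maps),
        error = function(e) stop("phantom ", i, " (stage: plan ",
                                 plan_types[j], "): ", conditionMessage(e)))
      row <- plan_metrics(plan, st)
      metrics[[length(metrics) + 1L]] <-
        cbind(data.frame(phantom = i, plan = plan_types[j]), row)
    }
  }
  list(metrics = do.call(rbind, metrics), depths = do.call(rbind, depths))
}

#' One-way analysis of variance with Tukey pairwise comparisons
#'
#' Standard between/within mean-square F test across groups, with
#' Tukey-HSD-style pairwise p values from the studentized range
#' distribution.  Implemented directly because it is part of the study
#' procedure; it agrees with `stats::aov` to numerical precision.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return An object of class `anova_result`: `F`, `p`, `df`, `group_means`,
#'   `pairwise` (data.frame with groups and p values).
#' @export
one_way_anova <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  if (ssw == 0) stop("degenerate groups: zero within-group variance")
  msw <- ssw / df2
  f <- (ssb / df1) / msw
  p <- pf(f, df1, df2, lower.tail = FALSE)
  pairs <- utils::combn(k, 2)
  pw <- data.frame(
    group1 = names(groups)[pairs[1, ]],
    group2 = names(groups)[pairs[2, ]],
    diff = means[pairs[2, ]] - means[pairs[1, ]],
    p = vapply(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      se <- sqrt(msw / 2 * (1 / n[i1] + 1 / n[i2]))
      q <- abs(means[i1] - means[i2]) / se
      ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    }, numeric(1)),
    row.names = NULL)
  structure(list(F = f, p = p, df = c(df1, df2), group_means = means,
                 pairwise = pw),
            class = "anova_result")
}

#' Summarize a cohort table: mean, SD and ANOVA p per metric
#'
#' Mean and sample SD (n - 1) per plan type for every numeric metric, plus
#' the one-way ANOVA p value across plan types, in the shape of the study's
#' summary tables.
#'
#' @param metrics the `metrics` data.frame from [run_cohort()].
#' @param columns metric columns to summarize; defaults to all numeric
#'   columns except identifiers.
#' @return data.frame: metric, plan, mean, sd, anova_p (p repeated within
#'   metric; NA when fewer than two plan types).
#' @export
summarize_cohort <- function(metrics, columns = NULL) {
  if (is.null(columns)) {
    num <- vapply(metrics, is.numeric, logical(1))
    columns <- setdiff(names(metrics)[num], c("phantom", "n_fields"))
  }
  plans <- unique(metrics$plan)
  out <- list()
  for (col in columns) {
    groups <- lapply(plans, function(p) metrics[[col]][metrics$plan == p])
    names(groups) <- plans
    p_anova <- if (length(plans) >= 2 &&
                   all(vapply(groups, length, 1L) >= 2) &&
                   sum(vapply(groups, function(g)
                     sum((g - mean(g))^2), numeric(1))) > 0)
      one_way_anova(groups)$p else NA_real_
    out[[col]] <- data.frame(
      metric = col, plan = plans,
      mean = vapply(groups, mean, numeric(1)),
      sd = vapply(groups, function(g)
        if (length(g) > 1) sd(g) else NA_real_, numeric(1)),
      anova_p = p_anova, row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
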