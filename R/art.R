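#' Aligned-rank-transform factorial ANOVA
#'
#' Nonparametric factorial ANOVA: for each effect of interest the response
#' is aligned (the full-model cell mean is subtracted and the effect's own
#' marginal estimate added back), ranked, and submitted to a standard
#' factorial ANOVA from which only that effect's row is read. Supports a
#' repeated-measures error stratum via `subject` (within-subject factors
#' nested under the subject).
#'
#' @param data A data frame.
#' @param response Name of the numeric response column.
#' @param factors Character vector of factor column names (2 or 3).
#' @param subject Optional subject column name for repeated measures.
#' @param within Character vector naming which `factors` are
#'   within-subject (defaults to all when `subject` is given).
#' @param effects Effects to report; default all mains and interactions.
#' @return A tibble with one row per effect: `term, df, df_resid,
#'   statistic, p.value`.
#' @export
#' @examples
#' d <- expand.grid(a = factor(1:2), b = factor(1:3), s = factor(1:8))
#' d$y <- rnorm(nrow(d)) + as.integer(d$a)
#' art_anova(d, "y", c("a", "b"))
art_anova <- function(data, response, factors, subject = NULL,
                      within = NULL, effects = NULL) {
  stopifnot(length(factors) >= 2, length(factors) <= 3)
  for (f in factors) data[[f]] <- factor(data[[f]])
  y <- data[[response]]
  if (!is.numeric(y)) stop("response must be numeric")

  cell_key <- interaction(data[factors], drop = TRUE)
  cell_mean <- stats::ave(y, cell_key)

  # marginal mean over a subset of factors (empty subset = grand mean)
  marg <- function(sub) {
    if (!length(sub)) return(rep(mean(y), length(y)))
    stats::ave(y, interaction(data[sub], drop = TRUE))
  }
  all_effects <- unlist(lapply(seq_along(factors), function(k) {
    utils::combn(factors, k, simplify = FALSE)
  }), recursive = FALSE)
  if (is.null(effects)) effects <- all_effects
  if (is.character(effects)) effects <- list(effects)

  form_rhs <- paste(factors, collapse = " * ")
  if (!is.null(subject)) {
    data[[subject]] <- factor(data[[subject]])
    if (is.null(within)) within <- factors
  }

  purrr::map_dfr(effects, function(eff) {
    # inclusion-exclusion estimate of this effect at each observation
    est <- rep(0, length(y))
    subs <- unlist(lapply(0:length(eff), function(k) {
      utils::combn(eff, k, simplify = FALSE)
    }), recursive = FALSE)
    for (s in subs) {
      est <- est + (-1)^(length(eff) - length(s)) * marg(s)
    }
    data$.aligned_rank <- rank(y - cell_mean + est)
    term <- paste(eff, collapse = ":")
    if (is.null(subject)) {
      fit <- aov(
        stats::as.formula(paste(".aligned_rank ~", form_rhs)),
        data = data
      )
      tab <- anova(fit)
      tibble::tibble(
        term = term, df = tab[term, "Df"],
        df_resid = tab["Residuals", "Df"],
        statistic = tab[term, "F value"], p.value = tab[term, "Pr(>F)"]
      )
    } else {
      w <- intersect(eff, within)
      err <- if (length(w)) {
        paste0("Error(", subject, "/(", paste(w, collapse = "*"), "))")
      } else {
        paste0("Error(", subject, ")")
      }
      # with one observation per subject x cell the lowest stratum is
      # empty and aov warns about singularity; the tested strata are fine
      fit <- suppressWarnings(aov(
        stats::as.formula(paste(".aligned_rank ~", form_rhs, "+", err)),
        data = data
      ))
      tabs <- summary(fit)
      for (stratum in tabs) {
        tab <- stratum[[1]]
        ix <- match(term, trimws(rownames(tab)))
        if (!is.na(ix) && !is.na(tab[ix, "F value"])) {
          return(tibble::tibble(
            term = term, df = tab[ix, "Df"],
            df_resid = tab[nrow(tab), "Df"],
            statistic = tab[ix, "F value"], p.value = tab[ix, "Pr(>F)"]
          ))
        }
      }
      tibble::tibble(
        term = term, df = NA_real_, df_resid = NA_real_,
        statistic = NA_real_, p.value = NA_real_
      )
    }
  })
}
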