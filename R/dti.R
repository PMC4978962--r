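#' Repeated-measures ANCOVA on per-tract DTI metrics
#'
#' For each (tract, metric) cell of a complete subject x session table, runs
#' the sex-adjusted repeated-measures ANCOVA in its difference-score form:
#' the within-subject pairing is absorbed by working with the per-subject
#' session difference `d = post - pre` and session mean `m = (pre + post)/2`.
#' The group x session interaction is the group term of `d ~ sex + group`
#' (identical to the within-subject stratum F of the mixed two-way model on
#' balanced data); the group main effect is the group term of
#' `m ~ sex + group`; the session main effect is the F of the intercept of
#' `d` regressed on centred sex and group contrasts (the adjusted mean
#' change).
#'
#' @param table a [simulate_dti_table()]-shaped data frame: columns
#'   `subject_id`, `session`, `tract`, `metric`, `value`.
#' @param design a [make_design()] roster.
#' @param p_adjust `"none"` (default) or `"BH"` to add Benjamini-Hochberg
#'   adjusted interaction p-values across tracts x metrics.
#' @return data frame with one row per (tract, metric):
#'   `F_group`, `p_group`, `F_session`, `p_session`, `F_interaction`,
#'   `p_interaction` (and `p_interaction_adj` for `p_adjust = "BH"`).
#' @export
rm_ancova_dti <- function(table, design, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  needed <- c("subject_id", "session", "tract", "metric", "value")
  if (!all(needed %in% names(table))) {
    .stopf("plvmotif_data_error", "table must have columns: %s",
           paste(needed, collapse = ", "))
  }
  cells <- unique(table[, c("tract", "metric")])
  sex_c <- as.numeric(design$sex == "M") - mean(design$sex == "M")
  group_c <- as.numeric(design$group == "bd") - mean(design$group == "bd")
  res <- lapply(seq_len(nrow(cells)), function(k) {
    sub <- table[table$tract == cells$tract[k] & table$metric == cells$metric[k], ]
    pre <- sub$value[match(paste(design$subject_id, "pre"),
                           paste(sub$subject_id, sub$session))]
    post <- sub$value[match(paste(design$subject_id, "post"),
                            paste(sub$subject_id, sub$session))]
    if (anyNA(pre) || anyNA(post)) {
      .stopf("plvmotif_incomplete_design",
             "incomplete subject x session crossing for tract %s, metric %s",
             cells$tract[k], cells$metric[k])
    }
    d <- post - pre
    m <- (post + pre) / 2
    if (stats::var(d) == 0 || stats::var(m) == 0) {
      .stopf("plvmotif_degenerate", "zero variance for tract %s, metric %s",
             cells$tract[k], cells$metric[k])
    }
    inter <- stats::anova(stats::lm(d ~ sex + group,
                                    data = cbind(design, d = d)))
    grp <- stats::anova(stats::lm(m ~ sex + group,
                                  data = cbind(design, m = m)))
    ses_fit <- summary(stats::lm(d ~ sex_c + group_c))
    t_int <- ses_fit$coefficients["(Intercept)", "t value"]
    df_res <- ses_fit$df[2]
    data.frame(tract = cells$tract[k], metric = cells$metric[k],
               F_group = grp["group", "F value"],
               p_group = grp["group", "Pr(>F)"],
               F_session = t_int^2,
               p_session = 2 * stats::pt(-abs(t_int), df_res),
               F_interaction = inter["group", "F value"],
               p_interaction = inter["group", "Pr(>F)"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (p_adjust == "BH") {
    out$p_interaction_adj <- stats::p.adjust(out$p_interaction, method = "BH")
  }
  class(out) <- c("rm_ancova_result", "data.frame")
  out
}
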