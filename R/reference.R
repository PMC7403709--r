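#' Reference cohort margins
#'
#' Patient-level reconstruction of the reference rectal-cancer cohort's
#' categorical composition: the primary dataset holds 61 non-PR and 59 PR
#' patients, the validation dataset 11 and 20, with the published per-class
#' gender, clinical T/N stage and CEA-level counts. These margins are the
#' source of [cohort_config()]'s default covariate frequencies. Only the
#' per-column margins are published, so the alignment of categories across
#' columns within a patient row is arbitrary; the table supports marginal
#' summaries and univariable association tests, not joint analyses.
#'
#' @param dataset `"primary"` or `"validation"`.
#' @return data.frame with columns `label`, `gender`, `t_stage`, `n_stage`,
#'   `cea`; one row per patient.
#' @export
reference_table1 <- function(dataset = c("primary", "validation")) {
  dataset <- match.arg(dataset)
  counts <- if (dataset == "primary") {
    list(
      `non-PR` = list(gender = c(male = 38, female = 23),
                      t_stage = c(T2 = 2, T3 = 23, T4 = 36),
                      n_stage = c(N0 = 6, N1 = 46, N2 = 9),
                      cea = c(normal = 30, abnormal = 31)),
      PR = list(gender = c(male = 42, female = 17),
                t_stage = c(T2 = 1, T3 = 26, T4 = 32),
                n_stage = c(N0 = 17, N1 = 31, N2 = 11),
                cea = c(normal = 38, abnormal = 21))
    )
  } else {
    list(
      `non-PR` = list(gender = c(male = 8, female = 3),
                      t_stage = c(T2 = 1, T3 = 4, T4 = 6),
                      n_stage = c(N0 = 2, N1 = 8, N2 = 1),
                      cea = c(normal = 5, abnormal = 6)),
      PR = list(gender = c(male = 14, female = 6),
                t_stage = c(T2 = 0, T3 = 7, T4 = 13),
                n_stage = c(N0 = 4, N1 = 11, N2 = 5),
                cea = c(normal = 9, abnormal = 11))
    )
  }
  blocks <- lapply(names(counts), function(cl) {
    cc <- counts[[cl]]
    n <- sum(cc$gender)
    stopifnot(sum(cc$t_stage) == n, sum(cc$n_stage) == n, sum(cc$cea) == n)
    data.frame(label = rep(cl, n),
               gender = rep(names(cc$gender), cc$gender),
               t_stage = rep(names(cc$t_stage), cc$t_stage),
               n_stage = rep(names(cc$n_stage), cc$n_stage),
               cea = rep(names(cc$cea), cc$cea),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
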