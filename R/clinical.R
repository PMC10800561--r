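#' Pearson chi-square test for a 2x2 contingency table
#'
#' Closed-form Pearson statistic
#' `X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the Yates
#' continuity correction replacing `(ad - bc)^2` by
#' `(|ad - bc| - N/2)^2` (floored at zero). `continuity = "auto"` applies
#' the correction when any expected cell count falls below 5, the common
#' small-sample convention; the published efficacy table mixes corrected
#' and uncorrected rows, so the explicit `"on"`/`"off"` modes exist to
#' reproduce each row as printed.
#'
#' @param a 2x2 integer matrix (groups in rows, event/non-event in
#'   columns), or the top-left count when `b`, `c`, `d` are given.
#' @param b,c,d Optional scalar counts completing the table row-wise.
#' @param continuity `"auto"`, `"on"` or `"off"`.
#' @return List with `statistic`, `p_value` (two-sided, chi-square with
#'   1 df), `df`, `continuity` (whether the correction was applied), and
#'   `expected` (expected counts).
#' @export
#' @examples
#' chi_square_2x2(2, 51, 8, 27, continuity = "on")   # relapse comparison
chi_square_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                           continuity = c("auto", "on", "off")) {
  continuity <- match.arg(continuity)
  m <- if (is.matrix(a)) a else matrix(base::c(a, b, c, d), 2, 2, byrow = TRUE)
  if (any(dim(m) != 2) || anyNA(m)) stop("need a 2x2 table", call. = FALSE)
  if (any(m < 0)) stop("counts must be nonnegative", call. = FALSE)
  n <- sum(m)
  rs <- rowSums(m); cs <- colSums(m)
  if (any(base::c(rs, cs) == 0)) {
    stop("chi-square test undefined: zero margin", call. = FALSE)
  }
  expected <- outer(rs, cs) / n
  correct <- switch(continuity, on = TRUE, off = FALSE,
                    auto = any(expected < 5))
  det <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  num <- if (correct) max(abs(det) - n / 2, 0)^2 else det^2
  stat <- n * num / (prod(rs) * prod(cs))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, continuity = correct, expected = expected)
}

.outcome_classes <- c("CR", "PR", "NR", "Relapse")

#' Tally 12-month treatment outcomes by arm
#'
#' Counts each arm's complete remission (CR), partial remission (PR), no
#' remission (NR) and relapse, with percentage rates. Records carry an
#' exclusive 12-month `outcome_class` plus a logical `relapsed` flag: the
#' flag is how a relapse that the source study counted within a remission
#' category (rather than as a separate 12-month class) is represented, so
#' the published marginals of both arms are reproducible under one
#' convention. Relapse tallies count the flag; overall remission is
#' CR + PR.
#'
#' @param records Data frame with columns `arm`, `outcome_class`
#'   (CR/PR/NR/Relapse) and optionally `relapsed` (defaults to
#'   `outcome_class == "Relapse"`).
#' @return An `efficacy_tally` data frame, one row per arm: `n`, counts
#'   `cr`, `pr`, `nr`, `relapse`, `overall`, and matching `*_pct` rates
#'   (`NaN`-flagged for an empty arm).
#' @export
#' @examples
#' classify_outcomes(fixture_cohort())
classify_outcomes <- function(records) {
  if (!all(c("arm", "outcome_class") %in% names(records))) {
    stop("records need 'arm' and 'outcome_class' columns", call. = FALSE)
  }
  bad <- setdiff(unique(records$outcome_class), .outcome_classes)
  if (length(bad)) {
    stop("unknown outcome class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(records$relapsed)) {
    records$relapsed <- records$outcome_class == "Relapse"
  }
  arms <- unique(records$arm)
  if (!length(arms)) {
    empty <- data.frame(arm = character(), n = integer(), cr = integer(),
                        pr = integer(), nr = integer(), relapse = integer(),
                        overall = integer(), cr_pct = numeric(),
                        pr_pct = numeric(), nr_pct = numeric(),
                        relapse_pct = numeric(), overall_pct = numeric())
    return(structure(empty, class = c("efficacy_tally", "data.frame")))
  }
  rows <- lapply(arms, function(a) {
    r <- records[records$arm == a, ]
    n <- nrow(r)
    cr <- sum(r$outcome_class == "CR")
    pr <- sum(r$outcome_class == "PR")
    nr <- sum(r$outcome_class == "NR")
    rel <- sum(r$relapsed)
    overall <- cr + pr
    pct <- function(x) 100 * x / n   # NaN when the arm is empty
    data.frame(arm = a, n = n, cr = cr, pr = pr, nr = nr, relapse = rel,
               overall = overall,
               cr_pct = pct(cr), pr_pct = pct(pr), nr_pct = pct(nr),
               relapse_pct = pct(rel), overall_pct = pct(overall))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("efficacy_tally", "data.frame"))
}

#' Adverse-event summary by arm
#'
#' Per-arm, per-event episode counts and percentage incidence, plus an
#' overall row per arm. Episodes are counted (a patient with two events
#' contributes two), matching how the clinical tables report them; the
#' denominator is the number of records in the arm.
#'
#' @param records Data frame with columns `arm` and `ae_list`
#'   (semicolon-separated adverse-event labels, empty string for none).
#' @return Data frame with columns `arm`, `ae`, `episodes`,
#'   `incidence_pct`; the `ae == "overall"` rows give each arm's total.
#' @export
safety_summary <- function(records) {
  if (!all(c("arm", "ae_list") %in% names(records))) {
    stop("records need 'arm' and 'ae_list' columns", call. = FALSE)
  }
  arms <- unique(records$arm)
  rows <- lapply(arms, function(a) {
    r <- records[records$arm == a, ]
    n <- nrow(r)
    events <- unlist(strsplit(r$ae_list[nzchar(r$ae_list)], ";", fixed = TRUE))
    tab <- if (length(events)) table(events) else table(character())
    out <- data.frame(arm = a,
                      ae = c(names(tab), "overall"),
                      episodes = c(as.integer(tab), length(events)))
    out$incidence_pct <- 100 * out$episodes / n
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Efficacy comparison table with chi-square p-values
#'
#' Mirrors the published efficacy layout: one row per outcome (CR, PR,
#' NR, relapse, overall) with both arms' counts and rates and the 2x2
#' chi-square p-value comparing them. The continuity-correction mode is
#' recorded per row; the published table mixes Yates-corrected rows
#' (relapse, overall) with uncorrected ones (CR, PR, NR), so the default
#' modes reproduce it and can be overridden.
#'
#' @param tally An `efficacy_tally` with exactly two arms (see
#'   [classify_outcomes()]).
#' @param modes Named character vector giving the correction mode
#'   (`"auto"`, `"on"`, `"off"`) per outcome row.
#' @return Data frame with columns `outcome`, per-arm counts and
#'   percentages, `p_value`, `continuity`.
#' @export
efficacy_table <- function(tally,
                           modes = c(cr = "off", pr = "off", nr = "off",
                                     relapse = "on", overall = "on")) {
  if (nrow(tally) != 2L) stop("need a two-arm tally", call. = FALSE)
  outcomes <- c("cr", "pr", "nr", "relapse", "overall")
  rows <- lapply(outcomes, function(o) {
    x1 <- tally[[o]][1]; x2 <- tally[[o]][2]
    n1 <- tally$n[1]; n2 <- tally$n[2]
    ct <- chi_square_2x2(x1, n1 - x1, x2, n2 - x2,
                         continuity = modes[[o]])
    data.frame(outcome = o,
               arm1 = tally$arm[1], count1 = x1,
               pct1 = tally[[paste0(o, "_pct")]][1],
               arm2 = tally$arm[2], count2 = x2,
               pct2 = tally[[paste0(o, "_pct")]][2],
               statistic = ct$statistic, p_value = ct$p_value,
               continuity = ct$continuity)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
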