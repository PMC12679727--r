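#' Estimate propensity scores for T2D status
#'
#' Logistic regression (maximum likelihood, logit link) of T2D status on the
#' matching covariates. Matching distance is taken on the linear-predictor
#' (log-odds) scale, which is better behaved in the tails than the
#' probability scale.
#'
#' Cohort presets for the matching covariates follow the source designs:
#' age, sex and residence area (CCDRFS); age, sex, race and survey cycle
#' (NHANES); age, sex and race (UKB).
#'
#' @param data data frame containing \code{treat} and the covariates.
#' @param covariates character vector of covariate column names (non-empty).
#' @param treat treatment indicator column (logical), default \code{"t2d"}.
#' @return object of class \code{propensity}: list with \code{score}
#'   (probabilities strictly in (0,1)), \code{lp} (log-odds) and the fitted
#'   \code{glm} in \code{model}.
#' @export
estimate_propensity <- function(data, covariates, treat = "t2d") {
  if (!length(covariates)) stop("covariates must be non-empty")
  miss <- setdiff(c(treat, covariates), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  fml <- stats::reformulate(covariates, response = treat)
  fit <- suppressWarnings(stats::glm(fml, data = data, family = stats::binomial()))
  p <- stats::fitted(fit)
  if (any(p < 1e-10 | p > 1 - 1e-10))
    stop("perfect (or quasi-perfect) separation in the propensity model; ",
         "consider exact matching on the offending covariate instead")
  structure(list(score = as.numeric(p),
                 lp = as.numeric(stats::qlogis(p)),
                 model = fit),
            class = "propensity")
}

#' Preset matching covariates per cohort dialect
#'
#' @param cohort one of \code{"CCDRFS"}, \code{"NHANES"}, \code{"UKB"}.
#' @return character vector of covariate names.
#' @export
matching_covariates <- function(cohort = c("CCDRFS", "NHANES", "UKB")) {
  switch(match.arg(cohort),
         CCDRFS = c("age", "sex", "residence"),
         NHANES = c("age", "sex", "race", "survey_cycle"),
         UKB    = c("age", "sex", "race"))
}

# union-find "next alive position" helpers operate on integer vectors and
# return both the found position and the compressed vector
.find_dir <- function(ptr, i) {
  r <- i
  while (ptr[r] != r) r <- ptr[r]
  while (ptr[i] != r) { j <- ptr[i]; ptr[i] <- r; i <- j }
  list(pos = r, ptr = ptr)
}

#' Greedy nearest-neighbour propensity matching
#'
#' Matches each case (T2D participant) to its \code{ratio} nearest unused
#' controls by absolute distance on the supplied score scale, without
#' replacement. Cases are processed in descending propensity order; exact
#' distance ties are broken at random (reproducibly, via \code{seed}). A case
#' keeps a partial match when eligible controls run short (so achieved ratios
#' can fall below the requested one); a case with no eligible control within
#' the caliper is dropped.
#'
#' @param scores numeric vector of matching scores for everyone (use the
#'   \code{lp} element of \code{\link{estimate_propensity}}), or a
#'   \code{propensity} object.
#' @param t2d logical vector: TRUE for cases.
#' @param ratio requested controls per case (default 2).
#' @param caliper optional maximum |score distance|; default none.
#' @param seed integer seed for tie breaking.
#' @return object of class \code{matched_cohort}: data frame \code{matches}
#'   with \code{id} (position in the input), \code{group} and \code{role}
#'   ("case"/"control"), plus \code{achieved_ratio} per retained case.
#' @export
nearest_neighbor_match <- function(scores, t2d, ratio = 2, caliper = NULL,
                                   seed = 1L) {
  if (inherits(scores, "propensity")) scores <- scores$lp
  if (length(scores) != length(t2d)) stop("scores and t2d lengths differ")
  if (ratio < 1 || ratio != round(ratio)) stop("ratio must be a positive integer")
  cases <- which(as.logical(t2d))
  ctrls <- which(!as.logical(t2d))
  if (!length(ctrls)) stop("zero controls available for matching")
  set.seed(seed)

  ordc <- order(scores[ctrls])
  cs <- scores[ctrls][ordc]          # sorted control scores
  cid <- ctrls[ordc]
  m <- length(cid)
  # rightp over 1..m+1 (m+1 = past-the-end sentinel), leftp over 0..m stored
  # with +1 offset (index 1 = sentinel "none to the left")
  rightp <- seq_len(m + 1L)
  leftp <- seq_len(m + 1L)

  case_order <- cases[order(scores[cases], decreasing = TRUE)]
  grp <- 0L
  out_id <- integer(0); out_grp <- integer(0); out_role <- character(0)
  achieved <- integer(0); achieved_case <- integer(0)

  for (cs_i in case_order) {
    x <- scores[cs_i]
    k <- findInterval(x, cs)        # cs[k] <= x < cs[k+1]
    picked <- integer(0)
    for (r in seq_len(ratio)) {
      fr <- .find_dir(rightp, min(k + 1L, m + 1L)); rightp <- fr$ptr
      fl <- .find_dir(leftp, k + 1L); leftp <- fl$ptr
      rpos <- fr$pos                 # position >= k+1, m+1 means none
      lpos <- fl$pos - 1L            # position <= k, 0 means none
      dR <- if (rpos <= m) abs(cs[rpos] - x) else Inf
      dL <- if (lpos >= 1L) abs(cs[lpos] - x) else Inf
      if (!is.finite(dR) && !is.finite(dL)) break
      take_right <- if (dR < dL) TRUE else if (dL < dR) FALSE
        else stats::runif(1) < 0.5
      pos <- if (take_right) rpos else lpos
      d <- if (take_right) dR else dL
      if (!is.null(caliper) && d > caliper) break
      picked <- c(picked, pos)
      rightp[pos] <- pos + 1L        # remove from both alive lists
      leftp[pos + 1L] <- pos
    }
    if (length(picked)) {
      grp <- grp + 1L
      out_id <- c(out_id, cs_i, cid[picked])
      out_grp <- c(out_grp, rep(grp, 1L + length(picked)))
      out_role <- c(out_role, "case", rep("control", length(picked)))
      achieved <- c(achieved, length(picked))
      achieved_case <- c(achieved_case, cs_i)
    }
  }
  structure(list(matches = data.frame(id = out_id, group = out_grp,
                                      role = out_role),
                 achieved_ratio = stats::setNames(achieved,
                                                  as.character(achieved_case)),
                 ratio = ratio),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  ng <- length(x$achieved_ratio)
  cat("Matched cohort: ", ng, " groups (1 case : <= ", x$ratio,
      " controls), ", sum(x$matches$role == "control"),
      " controls retained\n", sep = "")
  print(table(achieved_ratio = x$achieved_ratio))
  invisible(x)
}

#' Write a matched cohort as delimited text
#'
#' Columns: participant id, group id, role.
#'
#' @param matched a \code{matched_cohort}.
#' @param path output path.
#' @export
write_matched_cohort <- function(matched, path) {
  utils::write.csv(matched$matches, path, row.names = FALSE)
}

#' Covariate balance before and after matching
#'
#' Standardized mean difference per covariate,
#' SMD = (mean_case - mean_control) / pooled SD (pooled SD from the
#' before-matching case and control variances). Non-numeric covariates are
#' coerced via their dummy indicators' first level. A covariate with zero
#' pooled SD is reported as SMD 0 with \code{degenerate = TRUE}.
#'
#' @param data the original data frame.
#' @param matched a \code{matched_cohort} from
#'   \code{\link{nearest_neighbor_match}}.
#' @param covariates character vector of covariate names.
#' @param treat treatment column, default \code{"t2d"}.
#' @return data frame with \code{covariate}, \code{smd_before},
#'   \code{smd_after}, \code{degenerate}.
#' @export
balance_table <- function(data, matched, covariates, treat = "t2d") {
  if (!nrow(matched$matches)) stop("matched cohort is empty")
  t2d <- as.logical(data[[treat]])
  kept <- matched$matches
  smd <- function(v, case_idx, ctrl_idx) {
    v <- as.numeric(if (is.numeric(v)) v else v == sort(unique(v))[1])
    s <- sqrt((stats::var(v[t2d]) + stats::var(v[!t2d])) / 2)
    if (!is.finite(s) || s == 0) return(c(0, TRUE))
    c((mean(v[case_idx]) - mean(v[ctrl_idx])) / s, FALSE)
  }
  res <- t(vapply(covariates, function(cv) {
    v <- data[[cv]]
    before <- smd(v, which(t2d), which(!t2d))
    after <- smd(v, kept$id[kept$role == "case"],
                 kept$id[kept$role == "control"])
    c(before[1], after[1], before[2] || after[2])
  }, numeric(3)))
  data.frame(covariate = covariates, smd_before = res[, 1],
             smd_after = res[, 2], degenerate = as.logical(res[, 3]),
             row.names = NULL)
}
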