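# Precision-grip performance scoring and group statistics.

#' Force trace container
#'
#' @param samples force values (N)
#' @param rate samples per second
#' @param target target force level as a fraction of maximal voluntary
#'   contraction (MVC), in (0, 1)
#' @param mvc maximal voluntary contraction (N); the target line is
#'   `target * mvc`
#' @return object of class `force_trace`
#' @export
force_trace <- function(samples, rate, target = 0.10, mvc = 60) {
  if (length(samples) == 0) stop("empty force trace")
  if (rate <= 0) stop("rate must be positive")
  if (target <= 0 || target >= 1) stop("target must lie in (0, 1)")
  structure(list(samples = as.numeric(samples), rate = rate,
                 target = target, mvc = mvc,
                 duration = length(samples) / rate),
            class = "force_trace")
}

#' Score precision-grip performance from a force trace
#'
#' Tracking error is the root-mean-square deviation of the applied force
#' from the horizontal target line over the full trace; the performance
#' score is its reverse-coded natural logarithm, `-ln(rmse)`, so higher
#' scores mean better precision.
#'
#' @param trace a `force_trace`, or a numeric vector of force samples
#' @param target_level target line in the units of `samples`; defaults to
#'   `target * mvc` for a `force_trace`
#' @return list with `rmse` and `score`
#' @examples
#' tr <- force_trace(rep(6 + 1, 1200), rate = 100, target = 0.1, mvc = 60)
#' compute_precision_score(tr)  # rmse 1, score 0
#' @export
compute_precision_score <- function(trace, target_level = NULL) {
  if (inherits(trace, "force_trace")) {
    if (is.null(target_level)) target_level <- trace$target * trace$mvc
    samples <- trace$samples
  } else {
    samples <- as.numeric(trace)
    if (is.null(target_level)) stop("target_level required for bare samples")
  }
  if (length(samples) == 0) stop("empty force trace")
  rmse <- sqrt(mean((samples - target_level)^2))
  if (rmse == 0) stop("degenerate score: rmse is zero, log undefined")
  list(rmse = rmse, score = -log(rmse))
}

#' Group statistics for precision scores
#'
#' Classic one-way (pooled-variance) ANOVA across groups plus all pairwise
#' two-sided pooled-variance t-tests with Holm step-down adjustment for
#' multiplicity.
#'
#' @param scores numeric vector of performance scores
#' @param groups group labels (factor or character), same length
#' @return object of class `grip_stats`: `F` statistic, `df`
#'   (between, within), `p`, and `pairwise` data frame (group1, group2, t,
#'   df, p, p_holm)
#' @export
group_statistics <- function(scores, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two scores")
  if (length(scores) != length(groups)) stop("length mismatch")
  tab <- anova(lm(scores ~ groups))
  Fstat <- tab$`F value`[1]
  df <- c(between = tab$Df[1], within = tab$Df[2])
  p <- tab$`Pr(>F)`[1]
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   t = NA_real_, df = NA_real_, p = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    a <- scores[groups == pairs[1, k]]
    b <- scores[groups == pairs[2, k]]
    tt <- t.test(a, b, var.equal = TRUE)
    pw$t[k] <- unname(tt$statistic)
    pw$df[k] <- unname(tt$parameter)
    pw$p[k] <- tt$p.value
  }
  pw$p_holm <- p.adjust(pw$p, method = "holm")
  structure(list(F = Fstat, df = df, p = p, pairwise = pw),
            class = "grip_stats")
}

#' @export
print.grip_stats <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat("Pairwise pooled-variance t-tests (Holm-adjusted):\n")
  print(x$pairwise, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Read force traces from CSV
#'
#' Expects columns `time` and `force`; the sampling rate is inferred from
#' the median time step.
#'
#' @param path CSV file path
#' @param target,mvc passed to [force_trace()]
#' @return a `force_trace`
#' @export
read_force_csv <- function(path, target = 0.10, mvc = 60) {
  d <- read.csv(path)
  if (!all(c("time", "force") %in% names(d)))
    stop("CSV must contain 'time' and 'force' columns")
  rate <- 1 / stats::median(diff(d$time))
  force_trace(d$force, rate = rate, target = target, mvc = mvc)
}

#' Write a scores table to CSV
#'
#' @param scores data frame with at least subject_id, group, rmse, score
#' @param path output path
#' @return invisibly, the path
#' @export
write_scores_csv <- function(scores, path) {
  write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
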