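#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values \eqn{\tilde p_{(i)} = \min_{j \ge i}
#' \min(1, p_{(j)} m / j)}. NA entries are passed through without affecting
#' the ranks of the remaining values.
#'
#' @param p vector of p-values in [0, 1] (NAs allowed).
#' @return vector of adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

.contrast_model <- function(df) {
  df$condition <- factor(df$condition, levels = c("neutral", "fear"))
  fallback <- FALSE
  fit <- tryCatch(
    suppressWarnings(suppressMessages(lme4::lmer(
      value ~ condition + age + (1 | dataset_id / participant_id),
      data = df, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))),
    error = function(e) NULL
  )
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
    # with few dataset levels the dataset variance is often estimated at 0;
    # drop to a participant-only random intercept
    fallback <- TRUE
    fit <- tryCatch(
      suppressWarnings(suppressMessages(lme4::lmer(
        value ~ condition + age + (1 | participant_id),
        data = df, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = "ignore")))),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) {
    # degenerate residual variance (e.g. an exactly constant within-pair
    # shift): the paired-design limit, participant as a fixed factor
    fit <- tryCatch(
      stats::lm(value ~ condition + age + factor(participant_id), data = df),
      error = function(e) NULL
    )
  }
  list(fit = fit, fallback = fallback)
}

#' Mixed-model condition contrast for one node
#'
#' Fits \code{value ~ condition + age + (1 | dataset/participant)} (random
#' intercepts for dataset and participant nested in dataset) and returns the
#' age-adjusted fear-minus-neutral fixed-effect contrast. Negative \code{b}
#' means the metric is lower in the fear condition. If the nested fit is
#' singular (common with only 4 dataset levels) the model falls back to a
#' participant-only random intercept; \code{df} is the number of
#' participants minus 1.
#'
#' @param table long-format data.frame with columns \code{participant_id},
#'   \code{dataset_id}, \code{condition} (\code{"fear"}/\code{"neutral"}),
#'   \code{age}, \code{node_id}, and a \code{value} column (or a metric
#'   column named by \code{value_col}).
#' @param node node_id to fit (omit if \code{table} is already one node's
#'   rows).
#' @param value_col name of the response column (default \code{"value"}).
#' @return one-row data.frame: node_id, b, se, t, df, p, fallback
#'   (logical: participant-only random effect used). Statistics are NA if
#'   the model cannot be fit.
#' @export
fit_node_contrast <- function(table, node = NULL, value_col = "value") {
  df <- if (is.null(node)) table else table[table$node_id == node, ]
  if (!value_col %in% names(df))
    stop("no column '", value_col, "' in table", call. = FALSE)
  df$value <- df[[value_col]]
  if (nrow(df) == 0L) stop("no rows for node ", node, call. = FALSE)
  n_part <- length(unique(df$participant_id))
  res <- .contrast_model(df)
  node_id <- if (is.null(node)) df$node_id[1L] else node
  if (is.null(res$fit)) {
    return(data.frame(node_id = node_id, b = NA_real_, se = NA_real_,
                      t = NA_real_, df = NA_real_, p = NA_real_,
                      fallback = TRUE))
  }
  co <- summary(res$fit)$coefficients
  b <- co["conditionfear", "Estimate"]
  se <- co["conditionfear", "Std. Error"]
  dfree <- n_part - 1L
  tval <- b / se
  data.frame(node_id = node_id, b = b, se = se, t = tval, df = dfree,
             p = 2 * stats::pt(-abs(tval), dfree), fallback = res$fallback)
}

#' Mass-univariate node contrasts with FDR correction
#'
#' One mixed-model contrast per node (see [fit_node_contrast()]), then
#' Benjamini-Hochberg adjustment across all nodes of that metric.
#'
#' @param table long metrics table from [metrics_long_table()].
#' @param metric \code{"pc"} or \code{"bc"}.
#' @param node_table optional node table; if given, hemisphere/region/network
#'   columns are joined onto the result.
#' @return data.frame, one row per node: node_id, b, se, t, df, p, p_fdr,
#'   fallback (plus hemisphere, parcel_name, network if \code{node_table}
#'   given), ordered by node_id.
#' @export
run_mass_univariate <- function(table, metric = c("pc", "bc"),
                                node_table = NULL) {
  metric <- match.arg(metric)
  value_col <- paste0("mean_", metric)
  nodes <- sort(unique(table$node_id))
  rows <- lapply(nodes, function(nd)
    tryCatch(fit_node_contrast(table, nd, value_col),
             error = function(e)
               data.frame(node_id = nd, b = NA_real_, se = NA_real_,
                          t = NA_real_, df = NA_real_, p = NA_real_,
                          fallback = TRUE)))
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_adjust(out$p)
  if (!is.null(node_table)) {
    idx <- match(out$node_id, node_table$node_id)
    out$hemisphere <- node_table$hemisphere[idx]
    out$parcel_name <- node_table$parcel_name[idx]
    out$network <- node_table$network[idx]
  }
  out
}

#' Condition contrast for a global metric
#'
#' Same mixed model as [fit_node_contrast()], applied to one scalar metric
#' per (participant, condition). Also reports the raw paired mean difference
#' (fear minus neutral).
#'
#' @param table global metrics table from [metrics_global_table()].
#' @param metric \code{"e_global"} or \code{"q"}.
#' @return one-row data.frame: metric, mean_diff, b, se, t, df, p, fallback.
#' @export
fit_global_contrast <- function(table, metric = c("e_global", "q")) {
  metric <- match.arg(metric)
  value_col <- paste0("mean_", metric)
  if (!value_col %in% names(table))
    stop("table lacks column ", value_col, call. = FALSE)
  df <- table
  df$node_id <- 0L
  res <- fit_node_contrast(df, value_col = value_col)
  mean_diff <- mean(df[[value_col]][df$condition == "fear"]) -
    mean(df[[value_col]][df$condition == "neutral"])
  data.frame(metric = metric, mean_diff = mean_diff, b = res$b, se = res$se,
             t = res$t, df = res$df, p = res$p, fallback = res$fallback,
             stringsAsFactors = FALSE)
}
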