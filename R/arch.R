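#' Cost-function selection of a channel width
#'
#' Balances test error against model size over a width sweep:
#' `cost(alpha) = error(alpha) + lambda * params(alpha)` with
#' `lambda = sd(error) / sd(params)`, which puts the two addends on the same
#' scale across the sweep. The selected width minimizes the cost; ties are
#' broken toward the smaller parameter count (a free efficiency win).
#'
#' @param sweep a data frame of sweep points with columns `alpha` (channel
#'   width), `error` (mean HR RMSE, bpm), `params` (trainable-parameter
#'   count), and optionally `error_std`.
#' @return A `cost_result`: `lambda`, per-point `costs`, `alpha_star`, and
#'   the augmented sweep `table`.
#' @examples
#' tab <- data.frame(alpha = c(1, 2), error = c(2, 1), params = c(100, 1000))
#' compute_cost(tab)$alpha_star  # ties -> smaller-params point
#' @export
compute_cost <- function(sweep) {
  sweep <- as.data.frame(sweep)
  need <- c("alpha", "error", "params")
  if (!all(need %in% names(sweep)))
    stop("sweep needs columns ", paste(need, collapse = ", "))
  keep <- is.finite(sweep$error)
  if (sum(keep) < 2L) stop("need >= 2 sweep points with finite errors")
  sw <- sweep[keep, , drop = FALSE]
  sp <- stats::sd(sw$params)
  if (sp == 0) stop("lambda undefined: identical parameter counts across sweep")
  lambda <- stats::sd(sw$error) / sp
  costs <- sw$error + lambda * sw$params
  tol <- 1e-9 * max(1, abs(min(costs)))
  cand <- which(costs <= min(costs) + tol)
  best <- cand[which.min(sw$params[cand])]
  sw$cost <- costs
  structure(list(lambda = lambda,
                 costs = stats::setNames(costs, sw$alpha),
                 alpha_star = sw$alpha[best],
                 table = sw),
            class = "cost_result")
}

#' @export
print.cost_result <- function(x, ...) {
  cat(sprintf("<cost_result: lambda %.4g, alpha* = %s>\n",
              x$lambda, x$alpha_star))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Sweep the encoder or decoder channel width
#'
#' Sequential protocol: the encoder axis is swept with the decoder at its
#' baseline widths; the decoder axis is swept with the encoder fixed at its
#' previously selected width. For each width the supplied trainer is run
#' `repeats` times and the mean and standard deviation of the HR RMSE are
#' recorded together with the exact parameter count. A failed training run
#' is recorded as `NA` (with a warning), not fatal to the sweep.
#'
#' @param axis `"encoder"` or `"decoder"`.
#' @param widths integer widths to evaluate (conventionally powers of two
#'   from 1 to 64).
#' @param trainer `function(config, seed)` returning an HR RMSE in bpm.
#' @param repeats independent runs per width.
#' @param base_config the starting [channel_config] (default baseline).
#' @param encoder_width the fixed encoder width when sweeping the decoder.
#' @param seed base seed; run r at width w uses `seed + r`.
#' @return A data frame of sweep points (`alpha`, `error`, `error_std`,
#'   `params`, `n_ok`).
#' @export
sweep_channels <- function(axis = c("encoder", "decoder"), widths, trainer,
                           repeats = 10L,
                           base_config = preset_config("baseline"),
                           encoder_width = NULL, seed = 1L) {
  axis <- match.arg(axis)
  stopifnot(is.function(trainer), repeats >= 1L)
  rows <- lapply(widths, function(w) {
    cfg <- if (axis == "encoder") {
      channel_config(w, rep(w, 3), base_config$decoder_widths)
    } else {
      ew <- if (is.null(encoder_width)) base_config$encoder_widths[1] else encoder_width
      channel_config(ew, rep(ew, 3), rep(w, 2))
    }
    errs <- vapply(seq_len(repeats), function(r) {
      tryCatch(as.numeric(trainer(cfg, seed + r)),
               error = function(e) {
                 warning("training failed at width ", w, " (run ", r, "): ",
                         conditionMessage(e))
                 NA_real_
               })
    }, numeric(1))
    data.frame(alpha = w,
               error = mean(errs, na.rm = TRUE),
               error_std = stats::sd(errs[is.finite(errs)]),
               params = count_parameters(cfg),
               n_ok = sum(is.finite(errs)))
  })
  do.call(rbind, rows)
}

#' Write sweep results (with costs) to CSV
#'
#' @param sweep a [sweep_channels] data frame.
#' @param path output CSV path.
#' @return Invisibly, the [compute_cost] result.
#' @export
save_sweep <- function(sweep, path) {
  cr <- compute_cost(sweep)
  utils::write.csv(cr$table, path, row.names = FALSE)
  invisible(cr)
}
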