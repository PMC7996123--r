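# Generic threshold response machinery: rise (R) functions, rise-fall (RF)
# functions, and seeded random substreams.

#' Create a rise (R) response function
#'
#' A rise function is zero for inputs at or below its threshold and
#' non-decreasing above it.  Two concrete forms are supported:
#'
#' * `linear`: `s * max(x - p, 0)` with slope `s >= 0` and threshold `p >= 0`.
#' * `exponential_death`: `a * (exp(max(x - d, 0)) - 1)`, the form used for
#'   the death-rate response of a group's population flow to its HP pc stock
#'   (default `a = 0.001`, `d = 50`).
#'
#' A function with all parameters zero evaluates to 0 everywhere.
#'
#' @param form `"linear"` or `"exponential_death"`.
#' @param p,s Threshold and slope of the linear form.
#' @param a,d Scale and offset of the exponential form.
#' @return An object of class `rise_fn`.
#' @seealso [eval_rise()], [risefall_fn()], [function_bank()]
#' @export
#' @examples
#' f <- rise_fn("exponential_death", a = 0.001, d = 50)
#' eval_rise(f, 53)  # 0.001 * (exp(3) - 1)
rise_fn <- function(form = c("linear", "exponential_death"),
                    p = 0, s = 0, a = 0, d = 0) {
  form <- match.arg(form)
  if (form == "linear") {
    if (p < 0 || s < 0) stop("rise_fn: 'p' and 's' must be >= 0")
    fn <- list(form = form, p = p, s = s)
  } else {
    if (a < 0 || d < 0) stop("rise_fn: 'a' and 'd' must be >= 0")
    fn <- list(form = form, a = a, d = d)
  }
  structure(fn, class = "rise_fn")
}

#' Evaluate a rise function
#'
#' @param fn A [rise_fn()].
#' @param x Input value(s), `>= 0`.
#' @return Numeric value(s), zero for `x` at or below the threshold.
#' @export
eval_rise <- function(fn, x) {
  stopifnot(inherits(fn, "rise_fn"))
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("eval_rise: 'x' must be finite and >= 0")
  }
  if (fn$form == "linear") {
    fn$s * pmax(x - fn$p, 0)
  } else {
    fn$a * (exp(pmax(x - fn$d, 0)) - 1)
  }
}

#' Create a rise-fall (RF) response function
#'
#' Piecewise-linear response that is 0 up to `p1`, rises to `fm` at `pm`,
#' falls back to 0 at `p2`, and continues below zero with slope
#' `-fall_slope` beyond `p2`.  Requires `0 <= p1 <= pm <= p2`.  With all
#' parameters zero the function is identically zero.
#'
#' @param p1,pm,p2 Breakpoints, `0 <= p1 <= pm <= p2`.
#' @param fm Peak value at `pm`, `>= 0`.
#' @param fall_slope Slope of the decline beyond `p2`, `>= 0`.
#' @return An object of class `risefall_fn`.
#' @export
risefall_fn <- function(p1 = 0, pm = 0, p2 = 0, fm = 0, fall_slope = 0) {
  if (p1 < 0 || fm < 0 || fall_slope < 0) {
    stop("risefall_fn: parameters must be >= 0")
  }
  if (!(p1 <= pm && pm <= p2)) {
    stop("risefall_fn: need p1 <= pm <= p2")
  }
  structure(list(p1 = p1, pm = pm, p2 = p2, fm = fm,
                 fall_slope = fall_slope),
            class = "risefall_fn")
}

#' Evaluate a rise-fall function
#'
#' @param fn A [risefall_fn()].
#' @param x Input value(s), `>= 0`.
#' @return Numeric value(s): 0 on `[0, p1]`, `fm` at `pm`, 0 at `p2`,
#'   negative beyond `p2`.
#' @export
eval_risefall <- function(fn, x) {
  stopifnot(inherits(fn, "risefall_fn"))
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("eval_risefall: 'x' must be finite and >= 0")
  }
  vapply(x, function(xi) {
    if (xi <= fn$p1) return(0)
    if (xi <= fn$pm) {
      if (fn$pm == fn$p1) return(fn$fm)
      return(fn$fm * (xi - fn$p1) / (fn$pm - fn$p1))
    }
    if (xi <= fn$p2) {
      if (fn$p2 == fn$pm) return(0)
      return(fn$fm * (fn$p2 - xi) / (fn$p2 - fn$pm))
    }
    -fn$fall_slope * (xi - fn$p2)
  }, numeric(1))
}

#' Bank of indexed response functions
#'
#' The model addresses 49 rise functions (`R1`...`R49`) and 24 rise-fall
#' functions (`RF1`...`RF24`) by index.  By default every function is the
#' all-zero function except the three death-rate responses `R29`, `R48`,
#' and `R49`, which use the exponential form with scale 0.001 and HP pc
#' death threshold 50.
#'
#' @param overrides Named list; names like `"R5"` or `"RF3"` mapped to
#'   [rise_fn()] / [risefall_fn()] objects replacing the defaults.
#' @param death_a,death_d Scale and threshold of the death-rate responses.
#' @return An object of class `function_bank` with elements `R` (list of
#'   49) and `RF` (list of 24).
#' @export
function_bank <- function(overrides = list(), death_a = 0.001, death_d = 50) {
  R <- lapply(seq_len(49), function(i) rise_fn("linear"))
  for (i in c(29L, 48L, 49L)) {
    R[[i]] <- rise_fn("exponential_death", a = death_a, d = death_d)
  }
  RF <- lapply(seq_len(24), function(i) risefall_fn())
  bank <- structure(list(R = R, RF = RF), class = "function_bank")
  for (nm in names(overrides)) {
    idx <- as.integer(sub("^RF?", "", nm))
    if (grepl("^RF", nm)) {
      stopifnot(inherits(overrides[[nm]], "risefall_fn"), idx %in% 1:24)
      bank$RF[[idx]] <- overrides[[nm]]
    } else if (grepl("^R", nm)) {
      stopifnot(inherits(overrides[[nm]], "rise_fn"), idx %in% 1:49)
      bank$R[[idx]] <- overrides[[nm]]
    } else {
      stop("function_bank: override names must look like 'R7' or 'RF3'")
    }
  }
  bank
}

# Internal shorthands used by the dynamics equations.
Rb <- function(bank, i, x) eval_rise(bank$R[[i]], x)
RFb <- function(bank, i, x) eval_risefall(bank$RF[[i]], x)

# ---------------------------------------------------------------------------
# Seeded random substreams.
#
# One master seed feeds five named substreams (conflict draws per site, HP
# chance draws per group) so that enabling randomness in one mechanism does
# not perturb the draw sequence of another.  Each substream keeps its own
# .Random.seed state; the caller's global RNG state is left untouched.

.substream_names <- c("origin_conflict", "destination_conflict",
                      "origin_hp_chance", "immigrant_hp_chance",
                      "native_hp_chance")

#' Create a seeded random stream with named substreams
#'
#' @param seed Integer master seed.
#' @return An environment of class `random_stream`.
#' @export
random_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  seed <- as.integer(seed)
  env <- new.env(parent = emptyenv())
  env$seed <- seed
  env$states <- new.env(parent = emptyenv())
  for (k in seq_along(.substream_names)) {
    sub_seed <- (abs(seed) + 1000003L * k) %% .Machine$integer.max
    env$states[[.substream_names[k]]] <- local({
      old <- .get_global_seed()
      set.seed(sub_seed)
      st <- get(".Random.seed", envir = globalenv())
      .restore_global_seed(old)
      st
    })
  }
  class(env) <- "random_stream"
  env
}

.get_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

.with_substream <- function(stream, substream, expr) {
  stopifnot(inherits(stream, "random_stream"),
            substream %in% .substream_names)
  old <- .get_global_seed()
  assign(".Random.seed", stream$states[[substream]], envir = globalenv())
  val <- force(expr)
  stream$states[[substream]] <- get(".Random.seed", envir = globalenv())
  .restore_global_seed(old)
  val
}

#' Draw from a substream
#'
#' `draw_uniform()` draws from Uniform(0, 1); `draw_normal()` from a
#' Normal with mean 0 and the given variance.  A variance of exactly 0
#' returns 0 without consuming a draw, so zero-variance runs are
#' bit-identical across seeds.
#'
#' @param stream A [random_stream()].
#' @param substream One of `"origin_conflict"`, `"destination_conflict"`,
#'   `"origin_hp_chance"`, `"immigrant_hp_chance"`, `"native_hp_chance"`.
#' @param variance Variance of the normal draw, `>= 0`.
#' @return A single numeric draw.
#' @export
draw_uniform <- function(stream, substream) {
  .with_substream(stream, substream, stats::runif(1))
}

#' @rdname draw_uniform
#' @export
draw_normal <- function(stream, substream, variance) {
  if (!is.finite(variance) || variance < 0) {
    stop("draw_normal: 'variance' must be finite and >= 0")
  }
  if (variance == 0) return(0)
  .with_substream(stream, substream, stats::rnorm(1, 0, sqrt(variance)))
}
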