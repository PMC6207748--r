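#' Piecewise time-course
#'
#' Rhythm parameters (heart rate, PR, QRS, QT) can vary over a recording:
#' drug scenarios are steps, anaesthetic washout is a ramp.  A `pw_profile`
#' holds breakpoints and per-segment interpolation: `"hold"` keeps the left
#' value until the next breakpoint (a step time-course) and `"linear"` ramps
#' between breakpoints.  Before the first breakpoint the first value applies;
#' after the last, the last value.
#'
#' @param time breakpoint times in seconds, strictly increasing.
#' @param value value at each breakpoint.
#' @param interp `"hold"` or `"linear"`, one per segment (recycled);
#'   `"step"` and `"ramp"` are accepted as aliases.
#' @return an object of class `pw_profile`.
#' @examples
#' hr <- pw_profile(c(0, 60), c(155, 116))      # step at t = 60 s
#' pw_eval(hr, c(30, 90))
#' @export
pw_profile <- function(time, value, interp = "hold") {
  stopifnot(length(time) == length(value), length(time) >= 1)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("pw_profile: breakpoint times must be strictly increasing")
  }
  interp[interp == "step"] <- "hold"
  interp[interp %in% c("ramp", "linear_ramp")] <- "linear"
  if (!all(interp %in% c("hold", "linear"))) {
    stop("pw_profile: interp must be 'hold' or 'linear'")
  }
  nseg <- max(1L, length(time) - 1L)
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 interp = rep_len(interp, nseg)),
            class = "pw_profile")
}

#' Evaluate a piecewise time-course
#' @param p a [pw_profile()] or a single number (treated as constant).
#' @param t times in seconds.
#' @return values at `t`.
#' @export
pw_eval <- function(p, t) {
  p <- as_pw_profile(p)
  n <- length(p$time)
  out <- numeric(length(t))
  seg <- findInterval(t, p$time)        # 0 = before first breakpoint
  out[seg == 0] <- p$value[1]
  out[seg >= n] <- p$value[n]
  inside <- which(seg >= 1 & seg < n)
  for (i in inside) {
    s <- seg[i]
    if (p$interp[s] == "hold") {
      out[i] <- p$value[s]
    } else {
      f <- (t[i] - p$time[s]) / (p$time[s + 1] - p$time[s])
      out[i] <- p$value[s] + f * (p$value[s + 1] - p$value[s])
    }
  }
  out
}

#' Coerce to a piecewise time-course
#' @param x a `pw_profile` or single numeric (constant profile).
#' @return a `pw_profile`.
#' @export
as_pw_profile <- function(x) {
  if (inherits(x, "pw_profile")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(pw_profile(0, x))
  stop("as_pw_profile: expected a pw_profile or a single number")
}

#' @export
print.pw_profile <- function(x, ...) {
  cat("<pw_profile>\n")
  print(data.frame(time_s = x$time, value = x$value,
                   interp = c(x$interp, NA)[seq_along(x$time)]))
  invisible(x)
}
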