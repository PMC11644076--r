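# shared internal helpers

# significance classes used throughout the package: ns / * / ** / ***
p_stars <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] <= 0.001, "***",
             ifelse(p[ok] <= 0.01, "**",
             ifelse(p[ok] <= 0.05, "*", "ns")))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_negative <- function(x, what) {
  if (any(!is.na(x) & x < 0))
    stop(sprintf("negative values in %s are not allowed", what), call. = FALSE)
  invisible(x)
}

# deterministic roman labels for tolerance groups
roman_group <- function(i) as.character(utils::as.roman(i))
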