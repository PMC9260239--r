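#' @keywords internal
"_PACKAGE"

## Condition helpers: every error raised by the package carries a class so
## callers (and tests) can distinguish grid mismatches from bad files etc.

nvc_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "nvc_error", "error")))
}

nvc_grid_error   <- function(msg) nvc_stop(msg, "nvc_grid_error")
nvc_format_error <- function(msg) nvc_stop(msg, "nvc_format_error")
nvc_config_error <- function(msg) nvc_stop(msg, "nvc_config_error")
nvc_data_error   <- function(msg) nvc_stop(msg, "nvc_data_error")
nvc_label_error  <- function(msg) nvc_stop(msg, "nvc_label_error")
nvc_index_error  <- function(msg) nvc_stop(msg, "nvc_index_error")

## Population (divide-by-n) standard deviation; the z-scoring convention
## used for all map normalization in this package.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

## Draw a sub-seed deterministically from the current RNG stream, keeping it
## within R's 32-bit integer range.
next_seed <- function() sample.int(.Machine$integer.max, 1L)
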