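# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed conditions so callers can distinguish schema from semantic failures
tc_error <- function(class, message, data = list()) {
  cond <- structure(
    class = c(class, "tc_error", "error", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  )
  stop(cond)
}

# whitespace normalization applied to every label before comparison
trim_label <- function(x) gsub("[[:space:]]+", " ", trimws(as.character(x)))

# unit separator: cannot appear in labels, safe as a key delimiter
KEY_SEP <- "\x1f"

paste_key <- function(...) paste(..., sep = KEY_SEP)

row_keys <- function(df, cols) {
  if (length(cols) == 0L) return(rep("", nrow(df)))
  do.call(paste, c(unname(as.list(df[cols])), list(sep = KEY_SEP)))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

assert_string <- function(x, what) {
  if (!is_string(x) || !nzchar(trimws(x)))
    tc_error("tc_semantic_error", sprintf("%s must be a nonempty string", what))
  invisible(x)
}
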