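#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# Round half away from zero at `digits` decimals. base::round() rounds half to
# even; score files are specified with conventional half-up rounding.
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Canonicalize an unordered gene pair so (A,B) == (B,A). Lexicographic order.
canonical_pair <- function(a, b) {
  swap <- a > b
  ga <- a
  ga[swap] <- b[swap]
  gb <- b
  gb[swap] <- a[swap]
  tibble(gene_a = ga, gene_b = gb)
}

# Canonicalize pair columns of a data frame in place.
canonicalize_pairs <- function(df, col_a = "gene_a", col_b = "gene_b") {
  cp <- canonical_pair(df[[col_a]], df[[col_b]])
  df[[col_a]] <- cp$gene_a
  df[[col_b]] <- cp$gene_b
  df
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

# Format a score for attribute/score files: fixed 3 decimals, half-up.
format_score <- function(x, digits = 3) {
  sprintf(paste0("%.", digits, "f"), round_half_up(x, digits))
}
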