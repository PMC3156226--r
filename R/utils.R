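#' @importFrom rlang abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join semi_join bind_rows distinct n row_number
#'   slice_max slice rename pull if_else across first last
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 pmap map_chr map_int map_dbl map_lgl keep
#' @importFrom stats setNames rbinom runif median quantile
#' @importFrom utils head tail
NULL

# Reverse-complement of a character vector of DNA strings (A,C,G,T,N kept).
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

# Byte-wise mismatch count between two equal-length strings.
count_mismatches <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Vectorised mismatch counting over pairs of equal-length strings.
count_mismatches_vec <- function(a, b) {
  if (length(a) == 0L) return(integer(0))
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

other_end <- function(end) ifelse(end == "L", "R", "L")

flip_orient <- function(o) ifelse(o == "F", "R", "F")

# Compose two relative orientations (F = same strand, R = opposite).
compose_orient <- function(o1, o2) ifelse(o1 == o2, "F", "R")

vertex_id <- function(read, end) paste0(read, "|", end)

# Vertex ids are "<read>|<end>" with an optional suffix appended when repeat
# duplication or bubble splitting privatises a vertex ("|L.c1.2", "|R*3").
vertex_read <- function(v) sub("\\|[LR]([.*].*)?$", "", v)

vertex_end <- function(v) sub("^.*\\|([LR])([.*].*)?$", "\\1", v)

`%||%` <- function(x, y) if (is.null(x)) y else x

# Pass-counter instrumentation: each full overlap-computation pass over a read
# pool increments a named counter.  Used to demonstrate that the left-over
# graph is built once and reused across blocks.
the_counters <- new.env(parent = emptyenv())

#' Reset or read overlap-pass counters
#'
#' The package counts every full overlap-computation pass over a read pool
#' (tagged e.g. `"leftover"` or `"local"`). This makes the efficiency contract
#' of the reusable left-over graph observable: assembling many blocks against
#' one left-over graph performs a single `"leftover"` pass.
#'
#' @return `overlap_pass_counts()` returns a named integer vector of counts.
#' @export
overlap_pass_counts <- function() {
  n <- ls(the_counters)
  setNames(vapply(n, function(k) get(k, envir = the_counters), integer(1)), n)
}

#' @rdname overlap_pass_counts
#' @export
reset_overlap_pass_counts <- function() {
  rm(list = ls(the_counters), envir = the_counters)
  invisible(NULL)
}

bump_counter <- function(tag) {
  cur <- if (exists(tag, envir = the_counters)) get(tag, envir = the_counters) else 0L
  assign(tag, cur + 1L, envir = the_counters)
  invisible(cur + 1L)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}
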