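#' Enumerate consumption patterns
#'
#' Builds the full set of 2^k diet vectors in which the given food groups
#' range over every consumed/not-consumed combination and all other
#' groups are not consumed. Used to verify indicator score ranges by
#' exhaustive enumeration.
#'
#' @param codes Food-group codes to vary (k <= 22).
#' @return A tibble with 2^k rows and all 29 logical food-group columns.
#' @examples
#' pats <- enumerate_diets(c("eggs", "milk"))
#' nrow(pats)  # 4
#' @export
enumerate_diets <- function(codes) {
  all_codes <- food_group_codes()
  stopifnot(all(codes %in% all_codes), !anyDuplicated(codes))
  k <- length(codes)
  if (k > 22L) stop("Refusing to enumerate more than 2^22 patterns.",
                    call. = FALSE)
  n <- 2L^k
  m <- matrix(FALSE, n, length(all_codes),
              dimnames = list(NULL, all_codes))
  bits <- 0:(n - 1L)
  for (j in seq_len(k)) {
    m[, codes[j]] <- bitwAnd(bits, bitwShiftL(1L, j - 1L)) > 0L
  }
  tibble::as_tibble(m)
}

#' Food groups entering an indicator
#'
#' @param indicator_id One of [indicator_ids()].
#' @return Character vector of the constituent food-group codes (union of
#'   the indicator's item sets).
#' @export
indicator_groups <- function(indicator_id) {
  unique(unlist(indicator_membership(indicator_id)$items$groups))
}
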