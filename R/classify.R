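#' Classify disability from BADL and IADL items
#'
#' Maps the ten activities-of-daily-living items to a living state code.
#' The five basic activities (BADL: bathing, dressing, eating, toileting,
#' indoor transferring) define severe disability: needing help on any one of
#' them returns state 2. A respondent independent in all BADLs but needing
#' help on any of the five instrumental activities (IADL: visiting
#' neighbours, shopping for groceries, washing clothes, preparing meals,
#' taking public transportation) is mildly disabled (state 1). Independence
#' in all ten items is no disability (state 0).
#'
#' @param badl numeric/logical vector of length 5; 1 (or TRUE) means the item
#'   needs help, 0 means independent.
#' @param iadl numeric/logical vector of length 5, same coding.
#' @return Integer state code 0, 1 or 2.
#' @details Classification requires all ten items: any missing item raises an
#'   error of class `eldertrans_classification_undefined`, leaving the caller
#'   to decide between exclusion and imputation.
#' @examples
#' classify_disability(badl = rep(0, 5), iadl = rep(0, 5)) # 0
#' classify_disability(badl = c(0, 0, 1, 0, 0), iadl = rep(0, 5)) # 2
#' @export
classify_disability <- function(badl, iadl) {
  if (length(badl) != 5L || length(iadl) != 5L) {
    stop("expected exactly 5 BADL and 5 IADL items")
  }
  items <- c(badl, iadl)
  if (anyNA(items)) {
    stop(structure(
      class = c("eldertrans_classification_undefined", "error", "condition"),
      list(message = "disability classification undefined: missing ADL item(s)",
           call = sys.call(-1))
    ))
  }
  if (!all(items %in% c(0, 1))) stop("ADL items must be 0/1 (or logical)")
  if (any(badl == 1)) return(2L)
  if (any(iadl == 1)) return(1L)
  0L
}
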