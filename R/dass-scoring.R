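## DASS-42 scoring: 42 items answered 0-3, three 14-item subscales
## (depression, anxiety, stress), each totalled to 0-42; higher = worse.

#' Standard DASS-42 item-to-subscale key
#'
#' The conventional assignment of the 42 items to the depression, anxiety and
#' stress subscales (14 items each). A different key with the same shape can
#' be passed to [score_dass()].
#'
#' @return data.frame with columns `item` (1..42) and `subscale`.
#' @export
dass42_key <- function() {
  depression <- c(3, 5, 10, 13, 16, 17, 21, 24, 26, 31, 34, 37, 38, 42)
  anxiety <- c(2, 4, 7, 9, 15, 19, 20, 23, 25, 28, 30, 36, 40, 41)
  stress <- c(1, 6, 8, 11, 12, 14, 18, 22, 27, 29, 32, 33, 35, 39)
  key <- data.frame(item = c(depression, anxiety, stress),
                    subscale = rep(c("depression", "anxiety", "stress"),
                                   each = 14),
                    stringsAsFactors = FALSE)
  key[order(key$item), ]
}

validate_dass_key <- function(key) {
  assert_that(all(c("item", "subscale") %in% names(key)),
              "key needs columns item, subscale")
  assert_that(setequal(key$item, 1:42) && !anyDuplicated(key$item),
              "key must assign each of items 1..42 exactly once")
  tab <- table(key$subscale)
  assert_that(length(tab) == 3 && all(tab == 14),
              "key must have three subscales of 14 items each")
  invisible(key)
}

#' Score DASS-42 responses into subscale totals
#'
#' @param items data.frame with `participant_id` and item columns
#'   `item_1`..`item_42`, responses coded 0-3.
#' @param key Item-to-subscale map, default [dass42_key()].
#' @param missing Either `"error"` (default: any missing response is a
#'   validation error naming the items) or `"prorate"` (a participant's
#'   missing items are imputed with the mean of their answered items on the
#'   same subscale, i.e. subscale total = 14 x mean of observed items;
#'   participants with a fully missing subscale are an error).
#' @return data.frame with `participant_id`, `stress`, `anxiety`,
#'   `depression`; each total in `[0, 42]`.
#' @export
score_dass <- function(items, key = dass42_key(),
                       missing = c("error", "prorate")) {
  missing <- match.arg(missing)
  validate_dass_key(key)
  assert_that("participant_id" %in% names(items),
              "items must carry a participant_id column")
  cols <- sprintf("item_%d", 1:42)
  absent <- setdiff(cols, names(items))
  assert_that(length(absent) == 0, "missing item column(s): %s",
              paste(absent, collapse = ", "))
  x <- as.matrix(items[, cols])
  storage.mode(x) <- "double"

  bad <- which(!is.na(x) & !(x %in% 0:3))
  if (length(bad)) stopf("responses outside {0,1,2,3} found (%d cells)",
                         length(bad))
  if (anyNA(x)) {
    if (missing == "error") {
      miss <- which(colSums(is.na(x)) > 0)
      stopf("missing responses in item(s): %s",
            paste(sub("item_", "", cols[miss]), collapse = ", "))
    }
  }

  out <- data.frame(participant_id = items$participant_id,
                    stringsAsFactors = FALSE)
  for (sub in c("stress", "anxiety", "depression")) {
    idx <- key$item[key$subscale == sub]
    block <- x[, idx, drop = FALSE]
    if (missing == "prorate") {
      n_obs <- rowSums(!is.na(block))
      assert_that(all(n_obs > 0),
                  "some participants have no observed %s items", sub)
      out[[sub]] <- rowMeans(block, na.rm = TRUE) * 14
    } else {
      out[[sub]] <- rowSums(block)
    }
  }
  out
}
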