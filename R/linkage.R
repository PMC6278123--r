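# Deterministic record linkage between two registries on the identity
# triple (patient name, mother's name, birth date): normalized exact
# matching with a manual-review queue for near-misses.

#' Normalize identity strings for linkage
#'
#' Upper-cases, strips diacritics (Latin-ASCII transliteration), collapses
#' runs of whitespace to a single space and trims the ends. Idempotent.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_name("  maria  da Silva ") # "MARIA DA SILVA"
#' normalize_name("JOSÉ")          # "JOSE"
normalize_name <- function(x) {
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  x <- toupper(x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Normalize an identity record
#'
#' Applies [normalize_name()] to the name fields of an identity data frame
#' (columns `full_name`, `mother_name`, `birth_date`); the birth date is left
#' unchanged. Unparseable birth dates become `NA` and are never silently
#' dropped: such records cannot auto-match (a missing field compares unequal)
#' and surface through the review queue instead.
#'
#' @param identities data frame with columns `full_name`, `mother_name`,
#'   `birth_date` (and any others, preserved).
#' @return the data frame with normalized name fields and `Date` birth dates.
#' @export
normalize_identity <- function(identities) {
  .check(all(c("full_name", "mother_name", "birth_date") %in% names(identities)),
         "identities must have full_name, mother_name, birth_date columns")
  identities$full_name <- normalize_name(identities$full_name)
  identities$mother_name <- normalize_name(identities$mother_name)
  identities$birth_date <- tryCatch(as.Date(identities$birth_date),
                                    error = function(e) {
                                      suppressWarnings(
                                        as.Date(as.character(identities$birth_date),
                                                format = "%Y-%m-%d"))
                                    })
  .check(all(nchar(identities$full_name) > 0) &&
           all(nchar(identities$mother_name) > 0),
         "identity names must be non-empty after normalization")
  identities
}

# equality that treats NA as "does not match"
.eq <- function(a, b) !is.na(a) & !is.na(b) & a == b

#' Link two registries on the normalized identity triple
#'
#' A cohort record is auto-matched to a surveillance record iff all three
#' normalized identity fields (full name, mother's name, birth date) are
#' equal — the "100% compatible" rule — and the triple is unambiguous: if
#' several records on either side tie for the same triple, none is
#' auto-matched and every tied pair goes to the review queue. Pairs agreeing
#' on exactly two of the three fields also enter the review queue for manual
#' adjudication (the near-miss signature of a typing error in the third
#' field). The queue is emitted, never auto-adjudicated.
#'
#' @param cohort_identities,surveillance_identities data frames with columns
#'   `code`, `full_name`, `mother_name`, `birth_date`; codes must be unique
#'   within each registry.
#' @return object of class `link_result`: list with
#'   `matched` (data frame `cohort_code`, `surveillance_code`),
#'   `unmatched_cohort`, `unmatched_surveillance` (code vectors), and
#'   `review_queue` (data frame `cohort_code`, `surveillance_code`,
#'   `n_fields_equal`, `reason` in `{"ambiguous_tie", "two_of_three"}`).
#' @export
link_identities <- function(cohort_identities, surveillance_identities) {
  for (nm in c("cohort", "surveillance")) {
    ids <- if (nm == "cohort") cohort_identities else surveillance_identities
    .check("code" %in% names(ids), nm, " identities must have a code column")
    .check(!anyDuplicated(ids$code),
           "duplicate codes within the ", nm, " registry")
  }
  a <- normalize_identity(cohort_identities)
  b <- normalize_identity(surveillance_identities)

  key <- function(d) paste(d$full_name, d$mother_name,
                           as.character(d$birth_date), sep = "\r")
  ka <- key(a); kb <- key(b)
  ka[is.na(a$birth_date)] <- NA
  kb[is.na(b$birth_date)] <- NA

  ta <- table(ka); tb <- table(kb)
  shared <- intersect(names(ta), names(tb))
  unique_shared <- shared[ta[shared] == 1 & tb[shared] == 1]
  tied_shared <- setdiff(shared, unique_shared)

  matched <- data.frame(
    cohort_code = a$code[match(unique_shared, ka)],
    surveillance_code = b$code[match(unique_shared, kb)],
    stringsAsFactors = FALSE
  )
  matched <- matched[order(matched$cohort_code), , drop = FALSE]
  rownames(matched) <- NULL

  # all cross pairs sharing a key, via a many-to-many merge on the key
  .pairs_on_key <- function(key_a, key_b, restrict = NULL) {
    da <- data.frame(ia = seq_along(key_a), k = key_a, stringsAsFactors = FALSE)
    db <- data.frame(ib = seq_along(key_b), k = key_b, stringsAsFactors = FALSE)
    da <- da[!is.na(da$k), , drop = FALSE]
    db <- db[!is.na(db$k), , drop = FALSE]
    if (!is.null(restrict)) da <- da[da$k %in% restrict, , drop = FALSE]
    merge(da, db, by = "k")[, c("ia", "ib"), drop = FALSE]
  }

  queue <- list()
  if (length(tied_shared)) {
    g <- .pairs_on_key(ka, kb, restrict = tied_shared)
    queue[[length(queue) + 1]] <- data.frame(
      cohort_code = a$code[g$ia], surveillance_code = b$code[g$ib],
      n_fields_equal = 3L, reason = "ambiguous_tie",
      stringsAsFactors = FALSE
    )
  }

  # 2-of-3 near misses: join on each field pair, require third field unequal
  two_of_three <- function(f1, f2, f3) {
    k2a <- paste(as.character(a[[f1]]), as.character(a[[f2]]), sep = "\r")
    k2b <- paste(as.character(b[[f1]]), as.character(b[[f2]]), sep = "\r")
    k2a[is.na(a[[f1]]) | is.na(a[[f2]])] <- NA
    k2b[is.na(b[[f1]]) | is.na(b[[f2]])] <- NA
    g <- .pairs_on_key(k2a, k2b)
    g <- g[!.eq(a[[f3]][g$ia], b[[f3]][g$ib]), , drop = FALSE]
    if (!nrow(g)) return(NULL)
    data.frame(
      cohort_code = a$code[g$ia], surveillance_code = b$code[g$ib],
      n_fields_equal = 2L, reason = "two_of_three",
      stringsAsFactors = FALSE
    )
  }
  queue <- c(queue,
             list(two_of_three("full_name", "mother_name", "birth_date"),
                  two_of_three("full_name", "birth_date", "mother_name"),
                  two_of_three("mother_name", "birth_date", "full_name")))
  queue <- queue[!vapply(queue, is.null, logical(1))]
  review_queue <- if (length(queue)) do.call(rbind, queue) else
    data.frame(cohort_code = character(), surveillance_code = character(),
               n_fields_equal = integer(), reason = character(),
               stringsAsFactors = FALSE)
  review_queue <- unique(review_queue)
  review_queue <- review_queue[order(review_queue$cohort_code,
                                     review_queue$surveillance_code), ,
                               drop = FALSE]
  rownames(review_queue) <- NULL

  structure(
    list(
      matched = matched,
      unmatched_cohort = sort(setdiff(a$code, matched$cohort_code)),
      unmatched_surveillance = sort(setdiff(b$code, matched$surveillance_code)),
      review_queue = review_queue
    ),
    class = "link_result"
  )
}

#' @export
print.link_result <- function(x, ...) {
  cat(sprintf(
    "link_result: %d auto-matched; %d / %d unmatched (cohort / surveillance); %d review-queue pairs\n",
    nrow(x$matched), length(x$unmatched_cohort),
    length(x$unmatched_surveillance), nrow(x$review_queue)))
  invisible(x)
}

#' Linkage recovery against ground truth
#'
#' @param result a `link_result`.
#' @param truth a truth `code_map` data frame (`cohort_code`,
#'   `surveillance_code`) as produced by [generate_paired_registries()].
#' @return list with `sensitivity` (true links auto-matched / true links) and
#'   `false_match_rate` (auto-matches not in truth / auto-matches; 0 when
#'   there are no auto-matches).
#' @export
linkage_recovery <- function(result, truth) {
  tr <- paste(truth$cohort_code, truth$surveillance_code, sep = "\r")
  got <- paste(result$matched$cohort_code, result$matched$surveillance_code,
               sep = "\r")
  sens <- if (length(tr)) sum(got %in% tr) / length(tr) else NA_real_
  fmr <- if (length(got)) sum(!(got %in% tr)) / length(got) else 0
  list(sensitivity = sens, false_match_rate = fmr)
}

#' Write linkage output as three CSV files
#'
#' @param result a `link_result`.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_link_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$matched, file.path(dir, "matched.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(registry = c(rep("cohort", length(result$unmatched_cohort)),
                            rep("surveillance", length(result$unmatched_surveillance))),
               code = c(result$unmatched_cohort, result$unmatched_surveillance),
               stringsAsFactors = FALSE),
    file.path(dir, "unmatched.csv"), row.names = FALSE)
  utils::write.csv(result$review_queue, file.path(dir, "review_queue.csv"),
                   row.names = FALSE)
  invisible(dir)
}
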