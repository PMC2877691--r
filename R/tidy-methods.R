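#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a call matrix into long form
#'
#' @param x A `bs_calls`.
#' @param ... Unused.
#' @return A tibble with `clone_id`, `position`, `call` (`M`/`U`/`X`).
#' @export
tidy.bs_calls <- function(x, ...) {
  if (length(x$clone_ids) == 0L) {
    return(tibble::tibble(clone_id = character(), position = integer(),
                          call = character()))
  }
  tibble::tibble(
    clone_id = rep(x$clone_ids, each = length(x$sites)),
    position = rep(x$sites, times = length(x$clone_ids)),
    call = as.vector(t(x$calls))
  )
}

#' @export
tidy.bs_summary <- function(x, ...) x$per_site

#' @export
glance.bs_summary <- function(x, ...) {
  tibble::tibble(
    overall_pct = x$overall_pct,
    informative_pct = x$informative_pct,
    n_clones = x$n_clones,
    n_sites = x$n_sites,
    min_site_n = x$min_site_n
  )
}

#' @export
tidy.bs_result <- function(x, ...) tidy(x$calls)

#' @export
glance.bs_result <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$summary),
    tibble::tibble(
      n_reads_input = sum(x$filter_log$stage == "alignment"),
      n_passed_quality = if (nrow(x$quality)) sum(x$quality$passed) else 0L,
      n_kept = length(x$calls$clone_ids)
    )
  )
}

#' @export
tidy.bs_repeat_result <- function(x, ...) {
  if (is.null(x$summaries)) {
    return(tibble::tibble(read_id = character(), meth_count = integer(),
                          per100bp = double(), aligned_span = integer(),
                          positions = character()))
  }
  x$summaries$per_read
}

#' @export
glance.bs_repeat_result <- function(x, ...) {
  tibble::tibble(
    yang_pct = x$yang_pct,
    naive_pct = x$naive_pct,
    mean_per100bp = if (!is.null(x$summaries)) x$summaries$mean_per100bp else NA_real_,
    n_reads_input = sum(x$filter_log$stage == "alignment"),
    n_analyzed = length(x$repeat_reads)
  )
}
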