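#' Per-taxon amplification and blocking profiles
#'
#' Each record is classified against a primer configuration (a primer
#' set, optionally with a blocking oligo) into one of four exclusive
#' states:
#' \describe{
#'   \item{AMPLIFIED}{a complete amplicon is found and, if a blocking
#'     oligo is supplied, the oligo has no site inside it}
#'   \item{BLOCKED}{a complete amplicon is found but the blocking oligo
#'     binds within it, so the product is suppressed}
#'   \item{INCOMPLETE}{only one primer has a site, or the sites are
#'     mis-ordered: a truncated reference record}
#'   \item{NO_SITE}{neither primer has a site}
#' }
#'
#' @name specificity_profile
NULL

.STATUSES <- c("AMPLIFIED", "BLOCKED", "NO_SITE", "INCOMPLETE")

#' Classify one record against a primer configuration
#'
#' @param sequence Template string.
#' @param pset A [primer_set()].
#' @param blocking Optional blocking-oligo string; when supplied, a
#'   record whose amplicon contains a blocking site (within
#'   `block_max_mismatch`, either strand) is demoted from AMPLIFIED to
#'   BLOCKED.
#' @param max_mismatch Primer-matching allowance; defaults to the set's.
#' @param block_max_mismatch Blocking-site allowance (default 0).
#' @return List with `status` (one of AMPLIFIED, BLOCKED, NO_SITE,
#'   INCOMPLETE) and `amplicon_length` (NA unless a complete amplicon
#'   exists).
#' @export
classify_record <- function(sequence, pset, blocking = NULL,
                            max_mismatch = NULL, block_max_mismatch = 0L) {
  amps <- extract_amplicons(sequence, pset, max_mismatch)
  if (nrow(amps) > 0L) {
    amp <- amps[amps$primary, , drop = FALSE]
    status <- "AMPLIFIED"
    if (!is.null(blocking) &&
        nrow(find_primer_sites(amp$sequence, blocking, block_max_mismatch)) > 0L) {
      status <- "BLOCKED"
    }
    return(list(status = status, amplicon_length = amp$length))
  }
  if (is.null(max_mismatch)) max_mismatch <- pset$max_mismatch
  any_site <- nrow(find_primer_sites(sequence, pset$forward, max_mismatch)) > 0L ||
    nrow(find_primer_sites(sequence, pset$reverse, max_mismatch)) > 0L
  list(status = if (any_site) "INCOMPLETE" else "NO_SITE",
       amplicon_length = NA_integer_)
}

#' Classify every record of a database
#'
#' @param db Reference-database tibble.
#' @inheritParams classify_record
#' @return Tibble with columns record_id, status, amplicon_length.
#' @export
classify_db <- function(db, pset, blocking = NULL, max_mismatch = NULL,
                        block_max_mismatch = 0L) {
  validate_ref_db(db)
  res <- lapply(db$sequence, classify_record, pset = pset, blocking = blocking,
                max_mismatch = max_mismatch,
                block_max_mismatch = block_max_mismatch)
  tibble::tibble(
    record_id = db$id,
    status = vapply(res, `[[`, character(1L), "status"),
    amplicon_length = vapply(res, `[[`, integer(1L), "amplicon_length")
  )
}

#' Keep records carrying the complete amplicon region
#'
#' A record passes when both primer sites are found in amplifiable
#' orientation and the resulting product length falls inside
#' `length_bounds` (inclusive). This is a direct two-site criterion for
#' excluding partial SSU records.
#'
#' @param db Reference-database tibble.
#' @param pset A [primer_set()].
#' @param max_mismatch Primer-matching allowance; defaults to the set's.
#' @param length_bounds Numeric length-2 vector: plausible amplicon
#'   length interval for the marker.
#' @return The subset of `db` with complete amplicons, order preserved.
#' @export
completeness_filter <- function(db, pset, max_mismatch = NULL,
                                length_bounds = c(100L, 1000L)) {
  stopifnot(length(length_bounds) == 2L, length_bounds[1L] <= length_bounds[2L])
  cls <- classify_db(db, pset, blocking = NULL, max_mismatch = max_mismatch)
  keep <- cls$status == "AMPLIFIED" &
    !is.na(cls$amplicon_length) &
    cls$amplicon_length >= length_bounds[1L] &
    cls$amplicon_length <= length_bounds[2L]
  db[keep, , drop = FALSE]
}

#' A primer configuration for profiling
#'
#' @param pset A [primer_set()].
#' @param blocking Optional blocking-oligo string.
#' @param max_mismatch Primer allowance; defaults to the set's.
#' @param block_max_mismatch Blocking allowance (default 0).
#' @param name Configuration label; defaults to the set name, with
#'   "+BP" appended when a blocking oligo is present.
#' @return A `primer_config` list.
#' @export
primer_config <- function(pset, blocking = NULL, max_mismatch = NULL,
                          block_max_mismatch = 0L, name = NULL) {
  stopifnot(inherits(pset, "primer_set"))
  if (!is.null(blocking)) check_iupac(blocking, "blocking oligo")
  if (is.null(name)) {
    name <- if (is.null(blocking)) pset$name else paste0(pset$name, "+BP")
  }
  structure(list(name = name, pset = pset, blocking = blocking,
                 max_mismatch = max_mismatch,
                 block_max_mismatch = as.integer(block_max_mismatch)),
            class = "primer_config")
}

group_at_rank <- function(taxonomy, rank) {
  vapply(taxonomy, function(tx) {
    if (length(tx) >= rank) tx[[rank]] else "unresolved"
  }, character(1L))
}

#' Per-group amplification/blocking profile
#'
#' Classifies every record under each primer configuration and
#' aggregates counts per taxonomic group at the requested rank depth.
#' Records annotated shallower than `rank` are binned as "unresolved"
#' rather than dropped, so counts always sum to the database size.
#'
#' @param db Reference-database tibble.
#' @param configs A [primer_config()] or list of them.
#' @param rank 1-based taxonomy depth to group at (1 = root rank).
#' @return Tibble with one row per (config, group): n, per-status
#'   counts, `fraction_amplifiable` (complete amplicon, blocked or not),
#'   `fraction_amplified` (amplicon and not blocked) and
#'   `fraction_blocked`; groups ordered by descending size within each
#'   config.
#' @export
profile_groups <- function(db, configs, rank = 2L) {
  validate_ref_db(db)
  if (inherits(configs, "primer_config")) configs <- list(configs)
  stopifnot(all(vapply(configs, inherits, logical(1L), "primer_config")))
  groups <- group_at_rank(db$taxonomy, rank)
  out <- lapply(configs, function(cfg) {
    cls <- classify_db(db, cfg$pset, cfg$blocking, cfg$max_mismatch,
                       cfg$block_max_mismatch)
    tab <- table(group = groups,
                 status = factor(cls$status, levels = .STATUSES))
    counts <- as.data.frame.matrix(tab)
    tibble::tibble(
      config = cfg$name,
      group = rownames(counts),
      rank = rank,
      n = as.integer(rowSums(counts)),
      n_amplified = counts$AMPLIFIED,
      n_blocked = counts$BLOCKED,
      n_no_site = counts$NO_SITE,
      n_incomplete = counts$INCOMPLETE
    )
  })
  out <- dplyr::bind_rows(out)
  out$fraction_amplifiable <- (out$n_amplified + out$n_blocked) / out$n
  out$fraction_amplified <- out$n_amplified / out$n
  out$fraction_blocked <- out$n_blocked / out$n
  out <- out[order(match(out$config, vapply(configs, `[[`, character(1L), "name")),
                   -out$n, out$group), , drop = FALSE]
  out
}

#' Per-group comparison of two primer configurations
#'
#' @param profiles_a,profiles_b Single-configuration outputs of
#'   [profile_groups()] over the same records at the same rank.
#' @return Tibble with, per group, the two amplified fractions, their
#'   difference `delta_amplified` (A minus B, in [-1, 1]) and an
#'   `exclusive` flag set when exactly one configuration amplifies any
#'   record of the group.
#' @export
compare_primer_sets <- function(profiles_a, profiles_b) {
  for (p in list(profiles_a, profiles_b)) {
    if (length(unique(p$config)) != 1L) {
      stop("each profile table must contain exactly one configuration",
           call. = FALSE)
    }
  }
  if (!setequal(profiles_a$group, profiles_b$group) ||
      !identical(sort(profiles_a$n), sort(profiles_b$n))) {
    stop("profiles were not computed over the same records/groups", call. = FALSE)
  }
  b <- profiles_b[match(profiles_a$group, profiles_b$group), , drop = FALSE]
  tibble::tibble(
    group = profiles_a$group,
    n = profiles_a$n,
    fraction_amplified_a = profiles_a$fraction_amplified,
    fraction_amplified_b = b$fraction_amplified,
    delta_amplified = profiles_a$fraction_amplified - b$fraction_amplified,
    exclusive = xor(profiles_a$n_amplified > 0L, b$n_amplified > 0L)
  )
}
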