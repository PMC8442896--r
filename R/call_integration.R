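# Integration of per-approach evidence into species-level sex-chromosome
# calls, in a permissive flavour (everything detected) and a stringent
# flavour (excluding calls supported only by the WGS accumulation scan).

norm_calls <- function(x, tag) {
  if (is.null(x) || nrow(x) == 0L)
    return(data.frame(species_id = character(), lg_id = character(),
                      system = character(), evidence = character()))
  x <- as.data.frame(x)
  if (is.null(x$evidence)) x$evidence <- tag
  x[!is.na(x$species_id),
    c("species_id", "lg_id", "system", "evidence")]
}

#' Integrate approach-level calls into permissive and stringent call sets
#'
#' Per species, same-LG calls merge their evidence; different-LG calls with
#' the same heterogamety form one multi-LG (fusion-compatible) call;
#' different-LG calls with conflicting heterogamety keep the
#' transcriptome-supported side when there is one (conflict logged) and are
#' otherwise flagged.  The permissive set keeps every resolved call; the
#' stringent set drops calls whose only evidence is the WGS accumulation
#' scan (approach 2), prunes LGs supported only by approach 2 out of
#' multi-LG calls, and drops heterogamety-conflicted calls.
#'
#' @param a1,a2,a3 per-approach call data.frames with columns `species_id`,
#'   `lg_id`, `system` and optionally `evidence`.
#' @param literature optional side table of published calls (same columns),
#'   tagged `"literature"`.
#' @param all_species optional species universe used to report the
#'   no-signal list.
#' @return list with elements `permissive` and `stringent`, each a
#'   `call_set`: `flavor`, `calls` (one row per species: `species_id`,
#'   `lg_ids` semicolon-joined, `system`, `evidence`, `flag`), and
#'   `no_signal` species.
#' @export
integrate_calls <- function(a1 = NULL, a2 = NULL, a3 = NULL,
                            literature = NULL, all_species = NULL) {
  ev <- rbind(norm_calls(a1, "A1"), norm_calls(a2, "A2"),
              norm_calls(a3, "A3"), norm_calls(literature, "literature"))
  rows <- list()
  for (sp in unique(ev$species_id)) {
    e <- ev[ev$species_id == sp, ]
    systems <- unique(e$system)
    flag <- NA_character_
    if (length(systems) > 1L) {
      with_a3 <- unique(e$system[e$evidence == "A3"])
      if (length(with_a3) == 1L) {
        e <- e[e$system == with_a3, ]
        flag <- "heterogamety conflict; transcriptome call kept"
      } else {
        flag <- "heterogamety conflict"
        e <- e[e$system == names(sort(table(e$system),
                                      decreasing = TRUE))[1L], ]
      }
    }
    # per LG, evidence union; "unassigned" only kept when it is all there is
    by_lg <- split(e$evidence, e$lg_id)
    lg_ids <- names(by_lg)
    if (length(lg_ids) > 1L && "unassigned" %in% lg_ids) {
      by_lg <- by_lg[lg_ids != "unassigned"]
      lg_ids <- names(by_lg)
    }
    ev_by_lg <- lapply(by_lg, function(x) sort(unique(x)))
    rows[[sp]] <- list(species_id = sp, lg_ids = lg_ids,
                       ev_by_lg = ev_by_lg,
                       system = e$system[1L], flag = flag)
  }
  build_set <- function(flavor) {
    out <- list()
    for (r in rows) {
      ev_by_lg <- r$ev_by_lg
      lg_ids <- r$lg_ids
      if (flavor == "stringent") {
        if (!is.na(r$flag) && startsWith(r$flag, "heterogamety conflict"))
          next
        a2_only <- vapply(ev_by_lg, function(x) identical(x, "A2"), TRUE)
        if (all(a2_only)) next        # approach-2-exclusive call
        if (length(lg_ids) > 1L) {    # prune A2-only LGs from fusion calls
          lg_ids <- lg_ids[!a2_only]
          ev_by_lg <- ev_by_lg[!a2_only]
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        species_id = r$species_id,
        lg_ids = paste(lg_ids, collapse = ";"),
        system = r$system,
        evidence = paste(sort(unique(unlist(ev_by_lg))), collapse = ";"),
        flag = r$flag)
    }
    calls <- if (length(out) > 0L) do.call(rbind, out)
      else data.frame(species_id = character(), lg_ids = character(),
                      system = character(), evidence = character(),
                      flag = character())
    structure(list(flavor = flavor, calls = calls,
                   no_signal = setdiff(all_species, calls$species_id)),
              class = "call_set")
  }
  list(permissive = build_set("permissive"),
       stringent = build_set("stringent"))
}

#' Summarise a call set
#'
#' @param cs a `call_set` (or its `calls` data.frame).
#' @return list: `n_xy`, `n_zw`, `pct_xy` (percentage of called species
#'   with an XY system, 1 decimal), `per_lg` recruitment counts (each
#'   species counted once per recruited LG; `"unassigned"` excluded).
#' @export
summarize_calls <- function(cs) {
  calls <- if (inherits(cs, "call_set")) cs$calls else cs
  if (nrow(calls) == 0L)
    return(list(n_xy = 0L, n_zw = 0L, pct_xy = NA_real_,
                per_lg = table(character())))
  n_xy <- sum(calls$system == "XY")
  n_zw <- sum(calls$system == "ZW")
  lgs <- unlist(lapply(strsplit(calls$lg_ids, ";"), unique))
  lgs <- lgs[lgs != "unassigned" & !is.na(lgs)]
  list(n_xy = n_xy, n_zw = n_zw,
       pct_xy = round(100 * n_xy / (n_xy + n_zw), 1),
       per_lg = sort(table(lgs), decreasing = TRUE))
}
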