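#' Default salt / formulation suffixes stripped during name normalization
#'
#' Shipped as an editable text resource at
#' `system.file("extdata", "salt_suffixes.txt", package = "panscreen")`.
#' @return character vector of suffix tokens
#' @export
default_salt_suffixes <- function() {
  path <- system.file("extdata", "salt_suffixes.txt", package = "panscreen")
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Normalize a raw drug name
#'
#' Lowercases, collapses whitespace and punctuation, and optionally strips a
#' trailing salt/formulation suffix ("hydrochloride", "HCl", ...).
#' Deterministic: equal inputs always map to equal outputs.
#'
#' @param raw character vector of raw names
#' @param strip_salts logical; strip trailing salt suffixes
#' @param salt_suffixes suffix tokens to strip (already normalized)
#' @return character vector of normalized names
#' @export
normalize_drug_name <- function(raw, strip_salts = TRUE,
                                salt_suffixes = default_salt_suffixes()) {
  if (any(!nzchar(trimws(raw)))) stop("empty drug name")
  x <- tolower(trimws(raw))
  x <- gsub("[[:space:][:punct:]]+", "", x)
  if (strip_salts) {
    salts <- gsub("[[:space:][:punct:]]+", "", tolower(salt_suffixes))
    salts <- salts[order(nchar(salts), decreasing = TRUE)]
    for (s in salts) {
      hit <- endsWith(x, s) & nchar(x) > nchar(s)
      x[hit] <- substr(x[hit], 1L, nchar(x[hit]) - nchar(s))
    }
  }
  x
}

#' Merge drug identities across studies via an alias graph
#'
#' Builds an undirected graph whose nodes are normalized names, with edges
#' from (i) exact normalized-name matches across studies and (ii) a curated
#' synonym table, then iterates connected-component merging to a fixpoint:
#' after each pass, aliases shared by a merged identity induce new edges.
#' Components whose members carry contradictory curated canonical names are
#' split back along curated lines and flagged for review instead of merged.
#'
#' @param names_by_study named list: study_id -> character vector of raw
#'   drug names used in that study
#' @param synonym_table optional data.frame with columns alias, canonical
#'   (and optionally source); both sides are normalized before use
#' @param strict logical; if TRUE, unresolved curation conflicts are an error
#' @param salt_suffixes passed to [normalize_drug_name()]
#' @return list with `mapping` (data.frame raw_name, normalized, drug_id,
#'   study_id), `identities` (drug_id -> member normalized names),
#'   `conflicts` (data.frame of flagged splits)
#' @export
merge_drug_identities <- function(names_by_study, synonym_table = NULL,
                                  strict = FALSE,
                                  salt_suffixes = default_salt_suffixes()) {
  raw <- unlist(lapply(names(names_by_study), function(s) {
    stats::setNames(names_by_study[[s]], rep(s, length(names_by_study[[s]])))
  }))
  study <- names(raw)
  norm <- normalize_drug_name(raw, salt_suffixes = salt_suffixes)
  nodes <- sort(unique(norm))

  canonical_of <- character(0)   # normalized node -> curated canonical
  edges <- character(0)
  if (!is.null(synonym_table) && nrow(synonym_table) > 0) {
    a <- normalize_drug_name(synonym_table$alias, salt_suffixes = salt_suffixes)
    c_ <- normalize_drug_name(synonym_table$canonical,
                              salt_suffixes = salt_suffixes)
    contradictory <- tapply(c_, a, function(v) length(unique(v)) > 1)
    if (any(contradictory)) {
      bad <- names(contradictory)[contradictory]
      msg <- paste("contradictory curated canonicals for alias(es):",
                   paste(head(bad, 5L), collapse = ", "))
      if (strict) stop(msg) else warning(msg)
      keep <- !(a %in% bad)
      a <- a[keep]; c_ <- c_[keep]
    }
    canonical_of <- tapply(c_, a, function(v) v[1])
    canonical_of <- stats::setNames(as.character(canonical_of),
                                    names(canonical_of))
    nodes <- sort(unique(c(nodes, a, unname(canonical_of))))
    edges <- rbind(a, unname(canonical_of))
  }

  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (length(edges) > 0) g <- igraph::add_edges(g, as.vector(edges))

  # Fixpoint: merging by shared normalized names is exactly connected
  # components; iteration is needed only when a merge makes two members share
  # a curated canonical, adding an edge absent from the initial graph.
  repeat {
    comp <- igraph::components(g)$membership
    new_edges <- character(0)
    # nodes whose curated canonical falls in another component get an edge
    cur <- names(canonical_of)
    if (length(cur) > 0) {
      for (i in seq_along(cur)) {
        if (comp[cur[i]] != comp[canonical_of[[i]]])
          new_edges <- c(new_edges, cur[i], canonical_of[[i]])
      }
    }
    if (length(new_edges) == 0) break
    g <- igraph::add_edges(g, new_edges)
  }
  comp <- igraph::components(g)$membership

  # Conflict split: a component containing >1 distinct curated canonical is
  # suspect; split members along their curated canonical, leave uncurated
  # members with the component's majority canonical-free identity.
  conflicts <- data.frame(component = integer(0), member = character(0),
                          curated_canonical = character(0))
  identity_key <- as.character(comp)
  for (cid in unique(comp)) {
    members <- nodes[comp == cid]
    curated <- unique(unname(canonical_of[intersect(members,
                                                    names(canonical_of))]))
    curated <- curated[curated %in% nodes]
    if (length(curated) > 1) {
      for (m in members) {
        can <- if (m %in% names(canonical_of)) canonical_of[[m]]
          else if (m %in% curated) m else NA_character_
        identity_key[match(m, nodes)] <-
          paste0(cid, ":", ifelse(is.na(can), "unassigned", can))
        conflicts <- rbind(conflicts, data.frame(
          component = cid, member = m,
          curated_canonical = ifelse(is.na(can), "", can)))
      }
    }
  }
  if (nrow(conflicts) > 0 && strict)
    stop("unresolved drug-identity conflicts in ",
         length(unique(conflicts$component)), " component(s)")

  ids <- stats::setNames(paste0("D", match(identity_key,
                                           unique(identity_key))), nodes)
  mapping <- data.frame(raw_name = unname(raw), study_id = study,
                        normalized = norm,
                        drug_id = unname(ids[norm]),
                        stringsAsFactors = FALSE)
  identities <- split(nodes, unname(ids[nodes]))
  list(mapping = mapping, identities = identities, conflicts = conflicts)
}

#' Annotate drug mechanisms and targets from one or more sources
#'
#' Looks up each drug by any of its aliases in a mechanism table; target sets
#' are unioned over hits, and the mechanism list is ordered by source
#' priority then by within-source frequency. Drugs with no hit are flagged
#' unannotated rather than erroring.
#'
#' @param drugs data.frame with drug_id and list-column aliases (normalized)
#' @param mechanism_table data.frame with columns alias, mechanism, targets
#'   (semicolon-separated), source
#' @param priority character vector of source names, highest priority first
#' @return `drugs` with list-columns mechanisms, targets and logical
#'   `unannotated`
#' @export
annotate_mechanisms <- function(drugs, mechanism_table,
                                priority = unique(mechanism_table$source)) {
  mt <- mechanism_table
  mt$alias <- normalize_drug_name(mt$alias)
  mt$rank <- match(mt$source, priority)
  mt$rank[is.na(mt$rank)] <- length(priority) + 1L
  mechanisms <- vector("list", nrow(drugs))
  targets <- vector("list", nrow(drugs))
  for (i in seq_len(nrow(drugs))) {
    al <- normalize_drug_name(unlist(drugs$aliases[i]))
    hits <- mt[mt$alias %in% al, , drop = FALSE]
    if (nrow(hits) == 0) { mechanisms[[i]] <- character(0); targets[[i]] <- character(0); next }
    freq <- table(hits$mechanism)
    ord <- order(hits$rank, -as.numeric(freq[hits$mechanism]))
    mechanisms[[i]] <- unique(hits$mechanism[ord])
    targets[[i]] <- sort(unique(unlist(strsplit(hits$targets, ";", fixed = TRUE))))
  }
  drugs$mechanisms <- mechanisms
  drugs$targets <- targets
  drugs$unannotated <- lengths(mechanisms) == 0
  drugs
}

#' Filter a dataset to drugs screened in at least `min_studies` studies
#'
#' @param ds a `screen_dataset`
#' @param min_studies minimum number of distinct studies (>= 1)
#' @return a `screen_dataset` with attribute `filter_counts`
#'   (kept/dropped drug counts)
#' @export
filter_min_studies <- function(ds, min_studies = 3) {
  if (min_studies < 1) stop("min_studies must be >= 1")
  occ <- tapply(ds$records$study_id, ds$records$drug_id,
                function(s) length(unique(s)))
  keep <- names(occ)[occ >= min_studies]
  out <- ds
  out$records <- ds$records[ds$records$drug_id %in% keep, , drop = FALSE]
  rownames(out$records) <- NULL
  if (!is.null(out$drugs))
    out$drugs <- out$drugs[out$drugs$drug_id %in% keep, , drop = FALSE]
  attr(out, "filter_counts") <- c(kept = length(keep),
                                  dropped = length(occ) - length(keep))
  out
}
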