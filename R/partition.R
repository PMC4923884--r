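#' Pick the top-degree hub genes
#'
#' Ranks positive-degree nodes by degree (descending), breaking ties by
#' lexicographic gene id, and returns the first `k`.  A tie crossing the
#' rank-`k` boundary is resolved the same way and reported via a message so
#' the arbitrariness is visible in logs.
#'
#' @param net a `"gene_network"`.
#' @param k number of hubs (default 20).
#' @return character vector of `k` gene ids, in rank order.
#' @export
select_hubs <- function(net, k = 20L) {
  deg <- net$degree[net$degree >= 1L]
  if (length(deg) < k)
    stop("only ", length(deg), " nodes with degree >= 1; choose k <= ",
         length(deg))
  ord <- order(-deg, names(deg), method = "radix")
  ranked <- names(deg)[ord]
  if (length(deg) > k && deg[ranked[k]] == deg[ranked[k + 1L]])
    message("hub selection: tie at rank ", k, " (degree ",
            deg[ranked[k]], ") broken lexicographically")
  ranked[seq_len(k)]
}

#' Initialise one module per hub
#'
#' An initialised module is a hub gene together with all genes directly
#' connected to it in the network.
#'
#' @param net a `"gene_network"`.
#' @param hubs character vector of hub gene ids (see [select_hubs()]).
#' @return a list of `"initialized_module"` objects (fields `hub`,
#'   `members`, `hub_degree`), in the order of `hubs`.
#' @export
initialize_modules <- function(net, hubs) {
  missing <- setdiff(hubs, net$nodes)
  if (length(missing))
    stop("hubs absent from the network: ", paste(missing, collapse = ", "))
  lapply(hubs, function(h) {
    structure(list(hub = h,
                   members = sort(unique(c(h, neighbors_of(net, h)))),
                   hub_degree = unname(net$degree[h])),
              class = "initialized_module")
  })
}

#' Enumerate seed module sets
#'
#' A seed module set is a collection of two or more pairwise-disjoint
#' initialised modules.  By default all *maximal* such collections are
#' returned (maximal cliques of the disjointness graph over the modules), so
#' no returned set is contained in another; `maximal = FALSE` enumerates
#' every disjoint collection of size >= 2 for sensitivity analysis.
#'
#' @param mods list of `"initialized_module"` objects.
#' @param maximal return only maximal collections (default `TRUE`).
#' @return a list of seed sets, each an integer vector of indices into
#'   `mods`, deterministically ordered by the sorted hub-id lists.  Empty
#'   list when no two modules are disjoint.
#' @export
enumerate_seed_sets <- function(mods, maximal = TRUE) {
  n <- length(mods)
  if (n < 2L) stop("need at least 2 initialized modules")
  disj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L))
    for (j in seq(i + 1L, n))
      disj[i, j] <- disj[j, i] <-
        length(intersect(mods[[i]]$members, mods[[j]]$members)) == 0L
  g <- igraph::graph_from_adjacency_matrix(disj, mode = "undirected")
  cl <- if (maximal) igraph::max_cliques(g, min = 2L)
        else igraph::cliques(g, min = 2L)
  sets <- lapply(cl, function(v) sort(as.integer(v)))
  if (length(sets) == 0L) return(list())
  hubkey <- vapply(sets, function(s)
    paste(sort(vapply(mods[s], `[[`, "", "hub")), collapse = "\r"), "")
  sets[order(hubkey, method = "radix")]
}

#' Average pairwise overlap of a module collection
#'
#' The partition quality score: the mean intersection cardinality over all
#' unordered pairs of modules.  Well-separated partitions score low.
#'
#' @param modules list (length >= 2) of character vectors of gene ids.
#' @return a nonnegative number: sum of pairwise `|intersect|` divided by
#'   `choose(length(modules), 2)`.
#' @export
#' @examples
#' average_overlap(list(c("a", "b"), c("b", "c"), c("d")))
average_overlap <- function(modules) {
  a <- length(modules)
  if (a < 2L) stop("need at least 2 modules")
  tot <- 0
  for (i in seq_len(a - 1L))
    for (j in seq(i + 1L, a))
      tot <- tot + length(intersect(modules[[i]], modules[[j]]))
  tot / choose(a, 2L)
}

#' Grow a candidate partition from one seed set
#'
#' The remaining initialised modules (those not in the seed set) are merged
#' one by one into the seed-derived module with which they currently share
#' the most genes; after each merge the target module is updated to the
#' union, so later merges see the grown modules.  The remainder is processed
#' in a deterministic order (descending hub degree, ties by hub id) and
#' overlap ties go to the seed whose hub has the higher degree, then the
#' smaller id.
#'
#' A remaining module overlapping no seed-derived module (overlap 0
#' everywhere) is still merged into the tie-break seed under the default
#' `orphan_policy = "merge"`; `"standalone"` turns it into a module of its
#' own.  Either way the event is recorded in the merge log.
#'
#' @param seed_set integer vector of indices into `all_mods` (one element of
#'   [enumerate_seed_sets()] output).
#' @param all_mods list of all `"initialized_module"` objects.
#' @param orphan_policy `"merge"` (default) or `"standalone"`.
#' @param overlap `"cardinality"` (default, `|intersect|`) or `"jaccard"`.
#' @return an object of class `"module_partition"`: list with `modules`
#'   (named list of sorted gene-id vectors, names = seed hub ids),
#'   `seed_hubs`, `avg_overlap` and `merge_log` (data.frame `hub`,
#'   `target_seed`, `overlap`, `tie`, `orphan`).
#' @export
merge_remaining <- function(seed_set, all_mods,
                            orphan_policy = c("merge", "standalone"),
                            overlap = c("cardinality", "jaccard")) {
  orphan_policy <- match.arg(orphan_policy)
  overlap <- match.arg(overlap)
  if (any(seed_set < 1L | seed_set > length(all_mods)))
    stop("seed set indexes a module not present in all_mods")
  seeds <- all_mods[seed_set]
  rest <- all_mods[setdiff(seq_along(all_mods), seed_set)]

  cur <- lapply(seeds, `[[`, "members")
  names(cur) <- vapply(seeds, `[[`, "", "hub")
  seed_deg <- vapply(seeds, `[[`, 0, "hub_degree")

  if (length(rest)) {
    r_deg <- vapply(rest, `[[`, 0, "hub_degree")
    r_hub <- vapply(rest, `[[`, "", "hub")
    rest <- rest[order(-r_deg, r_hub, method = "radix")]
  }

  log <- data.frame(hub = character(), target_seed = character(),
                    overlap = numeric(), tie = logical(), orphan = logical(),
                    stringsAsFactors = FALSE)
  for (r in rest) {
    ov <- vapply(seq_along(cur), function(i) {
      inter <- length(intersect(r$members, cur[[i]]))
      if (overlap == "jaccard")
        inter / length(union(r$members, cur[[i]]))
      else as.numeric(inter)
    }, 0)
    best <- max(ov)
    cand <- which(ov == best)
    tie <- length(cand) > 1L
    if (tie) {
      ord <- order(-seed_deg[cand], names(cur)[cand], method = "radix")
      cand <- cand[ord]
    }
    target <- cand[1L]
    orphan <- best == 0
    if (orphan && orphan_policy == "standalone") {
      cur[[r$hub]] <- r$members
      seed_deg <- c(seed_deg, r$hub_degree)
      log <- rbind(log, data.frame(hub = r$hub, target_seed = r$hub,
                                   overlap = 0, tie = FALSE, orphan = TRUE,
                                   stringsAsFactors = FALSE))
      next
    }
    cur[[target]] <- sort(union(cur[[target]], r$members))
    log <- rbind(log, data.frame(hub = r$hub,
                                 target_seed = names(cur)[target],
                                 overlap = best, tie = tie, orphan = orphan,
                                 stringsAsFactors = FALSE))
  }
  cur <- lapply(cur, sort)
  e <- if (length(cur) >= 2L) average_overlap(cur) else 0
  structure(list(modules = cur,
                 seed_hubs = vapply(seeds, `[[`, "", "hub"),
                 avg_overlap = e, merge_log = log),
            class = "module_partition")
}

#' @exportS3Method base::print
print.module_partition <- function(x, ...) {
  cat("Module partition from seeds {", paste(x$seed_hubs, collapse = ", "),
      "}: ", length(x$modules), " modules, E = ",
      format(x$avg_overlap, digits = 6), "\n", sep = "")
  for (nm in names(x$modules))
    cat("  ", nm, ": ", length(x$modules[[nm]]), " genes\n", sep = "")
  invisible(x)
}

# canonical string for a module set (order-free equality)
partition_key <- function(part) {
  mods <- lapply(part$modules, sort)
  keys <- vapply(mods, paste, "", collapse = ",")
  paste(sort(keys), collapse = "|")
}

#' Adaptive partition of a network into functional modules
#'
#' The full partition algorithm: pick the top-`k` hubs, initialise one
#' module per hub, enumerate all seed module sets (maximal pairwise-disjoint
#' collections of initialised modules), grow one candidate partition per
#' seed set by overlap-greedy merging, score each candidate by its average
#' pairwise overlap E, and return every candidate attaining the minimum E
#' (distinct seed sets can produce identical best partitions; duplicates are
#' collapsed).
#'
#' @inheritParams merge_remaining
#' @param net a `"gene_network"`.
#' @param k number of hubs (default 20).
#' @return an object of class `"partition_result"`: list with `best` (list
#'   of `"module_partition"`, all attaining minimal E, deduplicated and
#'   deterministically ordered), `e_table` (data.frame `seed_set`, `hubs`,
#'   `n_modules`, `E`) and `k`.
#' @export
partition_network <- function(net, k = 20L,
                              orphan_policy = c("merge", "standalone"),
                              overlap = c("cardinality", "jaccard")) {
  orphan_policy <- match.arg(orphan_policy)
  overlap <- match.arg(overlap)
  hubs <- select_hubs(net, k)
  mods <- initialize_modules(net, hubs)
  sets <- enumerate_seed_sets(mods)
  if (length(sets) == 0L)
    stop("no seed module set: every pair of initialized modules overlaps. ",
         "Re-run penalty selection (penalty_scan) with a sparser penalty ",
         "or a finer grid.")
  parts <- lapply(sets, merge_remaining, all_mods = mods,
                  orphan_policy = orphan_policy, overlap = overlap)
  e <- vapply(parts, `[[`, 0, "avg_overlap")
  e_table <- data.frame(
    seed_set = seq_along(sets),
    hubs = vapply(sets, function(s)
      paste(vapply(mods[s], `[[`, "", "hub"), collapse = ","), ""),
    n_modules = vapply(parts, function(p) length(p$modules), 0L),
    E = e, stringsAsFactors = FALSE)
  best_idx <- which(e <= min(e) + 1e-12)
  best <- parts[best_idx]
  keys <- vapply(best, partition_key, "")
  best <- best[!duplicated(keys)]
  best <- best[order(vapply(best, partition_key, ""), method = "radix")]
  structure(list(best = best, e_table = e_table, k = k,
                 hubs = hubs), class = "partition_result")
}

#' @exportS3Method base::print
print.partition_result <- function(x, ...) {
  cat("Partition over k =", x$k, "hubs;", nrow(x$e_table),
      "seed set(s); best E =", format(min(x$e_table$E), digits = 6),
      "attained by", length(x$best), "distinct partition(s)\n")
  print(x$best[[1L]])
  invisible(x)
}

#' Write modules as a GMT-style gene-set file
#'
#' One line per module: module name, description (`seed_hub:<hub>`), then
#' the tab-separated gene list.
#'
#' @param part a `"module_partition"`.
#' @param path output path.
#' @param prefix module-name prefix (default `"module"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(part, path, prefix = "module") {
  stopifnot(inherits(part, "module_partition"))
  lines <- vapply(seq_along(part$modules), function(i) {
    paste(c(paste0(prefix, "_", i),
            paste0("seed_hub:", names(part$modules)[i]),
            part$modules[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#' @param path GMT path.
#' @return named list of character vectors (names = set names).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "", USE.NAMES = FALSE)
  sets
}
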