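# CNV unification: breakpoint-distance graph + iterative maximal-clique
# extraction. Calls of the same event from different platforms/pipelines have
# discordant breakpoints; calls whose start AND end each differ by less than a
# genomic window (default 100 bp) are treated as indistinguishable, and each
# maximal clique of mutually indistinguishable calls collapses to one unified
# CNV.

#' Breakpoint distance between CNV calls
#'
#' The Chebyshev distance on breakpoint pairs:
#' `max(|start_a - start_b|, |end_a - end_b|)`. Zero iff both endpoints agree
#' exactly. Defined only within a chromosome.
#'
#' @param a,b `cnv_records` tables, recycled element-wise.
#' @return Numeric vector of distances in bp.
#' @export
cnv_distance <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  if (any(normalize_chrom(a$chrom[ia]) != normalize_chrom(b$chrom[ib])))
    stop("cnv_distance is defined only for CNVs on the same chromosome")
  pmax(abs(a$start[ia] - b$start[ib]), abs(a$end[ia] - b$end[ib]))
}

#' Binary breakpoint similarity
#'
#' 1 when the breakpoint distance is strictly below the genomic window `gw`,
#' else 0. The boundary `distance == gw` is scored 0 (not similar): the window
#' is the lower limit distance at which two CNVs are distinguishable.
#'
#' @inheritParams cnv_distance
#' @param gw genomic window in bp (default 100).
#' @return Integer vector of 0/1.
#' @export
cnv_similarity <- function(a, b, gw = 100) {
  if (length(gw) != 1 || is.na(gw) || gw < 0) stop("gw must be a single nonnegative number")
  as.integer(cnv_distance(a, b) < gw)
}

#' Build the CNV similarity graph
#'
#' Nodes are record ids; an undirected edge joins two calls iff they lie on
#' the same chromosome, have the same type (a gain and a loss never merge),
#' and have breakpoint distance `< gw`. Candidate pairs are found by a sorted
#' sweep on start coordinates (`|start_a - start_b| < gw` is necessary), so
#' construction avoids the all-pairs quadratic blowup; the result equals the
#' naive all-pairs graph.
#'
#' @param cnvs a `cnv_records` table.
#' @param gw genomic window in bp.
#' @return An object of class `cnv_simgraph`: list with `nodes` (ids) and
#'   `edges` (two-column data.table of ids).
#' @export
build_similarity_graph <- function(cnvs, gw = 100) {
  if (length(gw) != 1 || is.na(gw) || gw < 0) stop("gw must be a single nonnegative number")
  edges <- list()
  if (nrow(cnvs) > 1) {
    dt <- data.table(id = cnvs$id, chrom = cnvs$chrom, start = cnvs$start,
                     end = cnvs$end, cnv_type = cnvs$cnv_type)
    setkey(dt, chrom, cnv_type, start)
    edges <- dt[, {
      ne <- .N
      if (ne > 1) {
        # sweep: j pairs with all later i while start difference < gw
        from <- integer(0); to <- integer(0)
        for (i in seq_len(ne - 1)) {
          j <- i + 1L
          while (j <= ne && start[j] - start[i] < gw) {
            if (abs(end[j] - end[i]) < gw) { from <- c(from, i); to <- c(to, j) }
            j <- j + 1L
          }
        }
        list(a = id[from], b = id[to])
      } else list(a = character(0), b = character(0))
    }, by = .(chrom, cnv_type)][, .(a, b)]
  } else {
    edges <- data.table(a = character(0), b = character(0))
  }
  structure(list(nodes = cnvs$id, edges = edges), class = "cnv_simgraph")
}

# deterministic key for clique tie-breaking: lexicographically smallest sorted
# member-id tuple ("\x01" separator sorts below printable ids in the C locale)
.clique_key <- function(ids) paste(sort(ids), collapse = "\x01")

#' Partition a similarity graph into cliques
#'
#' Iteratively removes a maximum clique from each connected component until no
#' node remains: the removed cliques are the groups of mutually identical
#' calls. Among equal-size maximum cliques the one with the lexicographically
#' smallest sorted member-id tuple is taken, so the partition is deterministic
#' regardless of internal enumeration order.
#'
#' @param g a `cnv_simgraph` from [build_similarity_graph()].
#' @return List of character vectors (sorted member ids); the vectors
#'   partition `g$nodes`.
#' @export
partition_into_cliques <- function(g) {
  if (length(g$nodes) == 0) return(list())
  gr <- igraph::graph_from_data_frame(
    d = g$edges, directed = FALSE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE)
  )
  out <- list()
  comp <- igraph::components(gr)
  for (ci in seq_len(comp$no)) {
    sub <- igraph::induced_subgraph(gr, which(comp$membership == ci))
    while (igraph::vcount(sub) > 0) {
      cl <- igraph::largest_cliques(sub)
      members <- lapply(cl, function(v) igraph::V(sub)$name[as.integer(v)])
      keys <- vapply(members, .clique_key, character(1))
      pick <- members[[which(keys == min(keys))[1]]]
      out[[length(out) + 1L]] <- sort(pick)
      sub <- igraph::delete_vertices(sub, pick)
    }
  }
  # stable output order: by smallest member id
  out[order(vapply(out, function(m) m[1], character(1)))]
}

# round-half-up median of coordinates
.median_coord <- function(x) floor(median(x) + 0.5)

#' Unify redundant CNV calls
#'
#' Full unification pipeline: similarity graph at window `gw`, clique
#' partition, then one unified CNV per clique. The representative interval
#' takes the per-coordinate median of member starts and ends (rounding half
#' up), robust to outlier breakpoints. Distinct carrier samples are counted
#' once per clique per ethnic group; records without a sample id each count
#' as their own carrier.
#'
#' @param cnvs a `cnv_records` table.
#' @param gw genomic window in bp (default 100).
#' @param group_sizes optional named vector of per-group sample counts; when
#'   supplied, per-group allele frequencies (`af_<GROUP>`) and `af_overall`
#'   are added via [group_allele_frequency()].
#' @return A `data.table` of class `unified_cnvs`: `chrom, start, end,
#'   cnv_type, n_members, n_samples, member_ids` (comma-joined) plus
#'   `carriers_<GROUP>` counts and, with `group_sizes`, AF columns.
#' @export
unify <- function(cnvs, gw = 100, group_sizes = NULL) {
  cliques <- partition_into_cliques(build_similarity_graph(cnvs, gw))
  groups <- xcnv_groups()
  rows <- lapply(cliques, function(ids) {
    m <- cnvs[match(ids, cnvs$id), ]
    carrier <- ifelse(is.na(m$sample_id), paste0(".anon.", m$id), m$sample_id)
    cg <- vapply(groups, function(g) length(unique(carrier[m$group == g])),
                 integer(1))
    c(list(chrom = m$chrom[1],
           start = .median_coord(m$start), end = .median_coord(m$end),
           cnv_type = m$cnv_type[1], n_members = nrow(m),
           n_samples = length(unique(carrier)),
           member_ids = paste(ids, collapse = ",")),
      as.list(setNames(as.integer(cg), paste0("carriers_", groups))))
  })
  u <- rbindlist(rows)
  if (nrow(u) == 0) {
    u <- data.table(chrom = character(0), start = numeric(0), end = numeric(0),
                    cnv_type = character(0), n_members = integer(0),
                    n_samples = integer(0), member_ids = character(0))
    for (g in groups) u[, paste0("carriers_", g) := integer(0)]
  }
  setattr(u, "class", c("unified_cnvs", class(data.table())))
  if (!is.null(group_sizes)) u <- group_allele_frequency(u, group_sizes)
  u[]
}

#' Per-group allele frequencies of unified CNVs
#'
#' The allele frequency within an ethnic group is the fraction of that group's
#' samples carrying the CNV (carrier frequency): `carriers_g / group_sizes[g]`.
#' `af_overall` is total distinct carriers over total samples.
#'
#' @param u a `unified_cnvs` table with `carriers_<GROUP>` columns.
#' @param group_sizes named vector of per-group sample counts; must cover (with
#'   a positive size) every group that has carriers.
#' @return `u` with `af_<GROUP>` columns and `af_overall` added.
#' @export
group_allele_frequency <- function(u, group_sizes) {
  groups <- xcnv_groups()
  present <- groups[vapply(groups, function(g) any(u[[paste0("carriers_", g)]] > 0),
                           logical(1))]
  missing_g <- setdiff(present, names(group_sizes)[group_sizes > 0])
  if (length(missing_g))
    stop("group_sizes missing or zero for group(s) with carriers: ",
         paste(missing_g, collapse = ", "))
  u <- copy(u)
  for (g in groups) {
    sz <- if (g %in% names(group_sizes)) group_sizes[[g]] else NA_real_
    u[, paste0("af_", g) := if (is.na(sz) || sz == 0) 0 else
      get(paste0("carriers_", g)) / sz]
  }
  u[, af_overall := n_samples / sum(group_sizes)]
  setattr(u, "class", c("unified_cnvs", class(data.table())))
  u[]
}
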