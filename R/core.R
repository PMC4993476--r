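#' Construct a vessel network object
#'
#' The central state object: a graph whose edges are vessel segments and
#' whose nodes carry positions, boundary roles and (after a flow solve)
#' blood pressures. Junctions never join more than three segments.
#'
#' @param nodes data.frame with columns `id` (integer), `x`, `y`, `z`
#'   (positions, um), `role` (one of `"interior"`, `"arterial_root"`,
#'   `"venous_root"`) and optionally `pressure` (mmHg, `NA` before a solve).
#' @param segments data.frame with columns `id`, `a`, `b` (node ids),
#'   `r` (radius, um), and optionally `r_tilde` (compressed radius, um;
#'   defaults to `r`), `l` (length, um; recomputed from node positions when
#'   missing), `H` (hematocrit), `q` (flow, um^3/s, signed positive a->b),
#'   `w` (wall stability, um), `type` (`"artery"`, `"vein"`, `"capillary"`),
#'   `tumor`, `sprout`, `boundary` (logicals), `tau` (sprout age, h),
#'   `tin` (residence time inside the tumor, h).
#' @param h_gen generation lattice constant (um).
#' @param h_fine fine lattice constant used during remodeling (um).
#' @param L lateral domain size (um); domain is (0, L)^3.
#' @param meta optional named list of extra metadata.
#' @return An object of class `vessel_network`.
#' @export
vessel_network <- function(nodes, segments, h_gen = 130, h_fine = 10,
                           L = NA_real_, meta = list()) {
  nodes <- as.data.frame(nodes)
  segments <- as.data.frame(segments)
  if (is.null(nodes$pressure)) nodes$pressure <- rep(NA_real_, nrow(nodes))
  nodes$pressure <- as.numeric(nodes$pressure)
  nodes$id <- as.integer(nodes$id)
  defaults <- list(r_tilde = NA_real_, H = 0.45, q = 0, w = 0,
                   type = "capillary", tumor = FALSE, sprout = FALSE,
                   boundary = FALSE, tau = 0, tin = 0)
  for (nm in names(defaults)) {
    if (is.null(segments[[nm]]))
      segments[[nm]] <- rep(defaults[[nm]], nrow(segments))
  }
  for (nm in c("r", "r_tilde", "H", "q", "w", "tau", "tin")) {
    segments[[nm]] <- as.numeric(segments[[nm]])
  }
  segments$id <- as.integer(segments$id)
  segments$a <- as.integer(segments$a)
  segments$b <- as.integer(segments$b)
  if (is.null(segments$l)) segments$l <- rep(NA_real_, nrow(segments))
  segments$l <- as.numeric(segments$l)
  net <- structure(list(nodes = nodes, segments = segments,
                        h_gen = h_gen, h_fine = h_fine, L = L, meta = meta),
                   class = "vessel_network")
  miss <- is.na(net$segments$l)
  if (any(miss)) net$segments$l[miss] <- segment_lengths(net)[miss]
  miss <- is.na(net$segments$r_tilde)
  net$segments$r_tilde[miss] <- net$segments$r[miss]
  net
}

#' @export
print.vessel_network <- function(x, ...) {
  nr <- sum(x$nodes$role != "interior")
  cat(sprintf(
    "<vessel_network> %d nodes (%d roots), %d segments, L = %s um\n",
    nrow(x$nodes), nr, nrow(x$segments),
    ifelse(is.na(x$L), "?", format(x$L))))
  invisible(x)
}

#' Euclidean lengths of all segments recomputed from node positions
#' @param net a `vessel_network`
#' @return numeric vector, um
#' @export
segment_lengths <- function(net) {
  ia <- match(net$segments$a, net$nodes$id)
  ib <- match(net$segments$b, net$nodes$id)
  sqrt((net$nodes$x[ia] - net$nodes$x[ib])^2 +
       (net$nodes$y[ia] - net$nodes$y[ib])^2 +
       (net$nodes$z[ia] - net$nodes$z[ib])^2)
}

#' Node degrees (number of incident segments)
#' @param net a `vessel_network`
#' @return integer vector aligned with `net$nodes`
#' @export
node_degrees <- function(net) {
  tab <- tabulate(c(match(net$segments$a, net$nodes$id),
                    match(net$segments$b, net$nodes$id)),
                  nbins = nrow(net$nodes))
  as.integer(tab)
}

#' Validate a vessel network against its structural invariants
#'
#' Checks: positive radii and lengths, stored length equal to the endpoint
#' distance, hematocrit in [0, 1], compressed radius not exceeding the
#' anatomical radius, non-negative wall stability, segment endpoints that
#' exist, no junction with more than three incident segments, positions
#' inside the domain, and the presence of at least one arterial and one
#' venous root.
#'
#' @param net a `vessel_network`
#' @param tol relative tolerance for the length check
#' @return character vector of violation descriptions; empty iff valid.
#' @export
validate_network <- function(net, tol = 1e-8) {
  v <- character()
  nd <- net$nodes; sg <- net$segments
  ia <- match(sg$a, nd$id); ib <- match(sg$b, nd$id)
  bad <- which(is.na(ia) | is.na(ib))
  for (i in bad) {
    v <- c(v, sprintf("segment %d: endpoint node missing (%d or %d)",
                      sg$id[i], sg$a[i], sg$b[i]))
  }
  ok <- setdiff(seq_len(nrow(sg)), bad)
  if (length(ok)) {
    li <- segment_lengths(net)[ok]
    for (i in ok[which(sg$r[ok] <= 0)])
      v <- c(v, sprintf("segment %d: non-positive radius", sg$id[i]))
    for (i in ok[which(li <= 0)])
      v <- c(v, sprintf("segment %d: zero length", sg$id[i]))
    rel <- abs(sg$l[ok] - li) / pmax(li, 1e-300)
    for (i in ok[which(li > 0 & rel > tol)])
      v <- c(v, sprintf("segment %d: stored length differs from endpoint distance",
                        sg$id[i]))
    for (i in ok[which(sg$H[ok] < 0 | sg$H[ok] > 1)])
      v <- c(v, sprintf("segment %d: hematocrit outside [0,1]", sg$id[i]))
    for (i in ok[which(sg$r_tilde[ok] > sg$r[ok] * (1 + 1e-12))])
      v <- c(v, sprintf("segment %d: compressed radius exceeds radius", sg$id[i]))
    for (i in ok[which(sg$w[ok] < 0)])
      v <- c(v, sprintf("segment %d: negative wall stability", sg$id[i]))
  }
  deg <- node_degrees(net)
  for (i in which(deg > 3))
    v <- c(v, sprintf("node %d: degree %d exceeds 3", nd$id[i], deg[i]))
  if (!is.na(net$L)) {
    out <- which(nd$x < -1e-9 | nd$x > net$L + 1e-9 |
                 nd$y < -1e-9 | nd$y > net$L + 1e-9 |
                 nd$z < -1e-9 | nd$z > net$L + 1e-9)
    for (i in out)
      v <- c(v, sprintf("node %d: position outside domain", nd$id[i]))
  }
  if (nrow(sg) > 0) {
    if (!any(nd$role == "arterial_root"))
      v <- c(v, "network: no arterial root")
    if (!any(nd$role == "venous_root"))
      v <- c(v, "network: no venous root")
  }
  v
}

.num_fmt <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

.write_table <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) .num_fmt(col) else as.character(col)
  })
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Save a vessel network as a plain-text container
#'
#' Writes a directory with `nodes.tsv`, `segments.tsv` and `meta.json`.
#' Numeric columns use 17 significant digits so that
#' `load_network(save_network(net, p))` reproduces every field bit-exactly.
#'
#' @param net a `vessel_network`
#' @param path directory to create/overwrite
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  .write_table(net$nodes, file.path(path, "nodes.tsv"))
  .write_table(net$segments, file.path(path, "segments.tsv"))
  meta <- c(list(h_gen = net$h_gen, h_fine = net$h_fine, L = net$L),
            net$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  np <- file.path(path, "nodes.tsv")
  sp <- file.path(path, "segments.tsv")
  mp <- file.path(path, "meta.json")
  for (f in c(np, sp, mp)) {
    if (!file.exists(f)) stop("network container incomplete: missing ", basename(f))
  }
  nodes <- utils::read.table(np, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  segments <- utils::read.table(sp, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  need_n <- c("id", "x", "y", "z", "role")
  need_s <- c("id", "a", "b", "r")
  if (!all(need_n %in% names(nodes)))
    stop("nodes.tsv: missing column(s) ",
         paste(setdiff(need_n, names(nodes)), collapse = ", "))
  if (!all(need_s %in% names(segments)))
    stop("segments.tsv: missing column(s) ",
         paste(setdiff(need_s, names(segments)), collapse = ", "))
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  extra <- meta[setdiff(names(meta), c("h_gen", "h_fine", "L"))]
  L <- if (is.null(meta$L)) NA_real_ else as.numeric(meta$L)
  vessel_network(nodes, segments, h_gen = as.numeric(meta$h_gen),
                 h_fine = as.numeric(meta$h_fine), L = L, meta = extra)
}
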