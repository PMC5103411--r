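## Plain-text persistence: TSV edge lists and NoN/NoSN bundle directories.

#' Read a weighted edge list from TSV
#'
#' Format: `node_a<TAB>node_b<TAB>weight` with the weight optional
#' (default 1.0); lines starting with `#` are comments, except that lines
#' of the form `#node<TAB>id` declare nodes explicitly (used to preserve
#' isolated nodes across round trips). Duplicate pairs are symmetrized by
#' the maximum weight.
#'
#' @param path TSV file path.
#' @return a [WeightedNetwork-class].
#' @export
readEdgeList <- function(path) {
  lines <- readLines(path)
  nodeDecl <- grep("^#node\t", lines, value = TRUE)
  declared <- sub("^#node\t", "", nodeDecl)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(lines)]
  if (!length(lines) && !length(declared))
    stop("empty edge list: ", path)
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    from <- vapply(parts, `[`, "", 1)
    to <- vapply(parts, `[`, "", 2)
    w <- vapply(parts, function(p)
      if (length(p) >= 3) as.numeric(p[3]) else 1.0, numeric(1))
    edges <- data.frame(from = from, to = to, weight = w)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  nodes <- sort(unique(c(edges$from, edges$to, declared)))
  networkFromEdges(edges, nodes)
}

#' Write a network as a TSV edge list
#'
#' Each unordered edge is written once; isolated nodes are preserved via
#' `#node` comment lines understood by [readEdgeList()].
#'
#' @param net a [WeightedNetwork-class].
#' @param path output file path.
#' @export
writeEdgeList <- function(net, path) {
  a <- .tsparse(adjacency(net))
  keep <- a@i < a@j
  i <- a@i[keep] + 1L; j <- a@j[keep] + 1L; w <- a@x[keep]
  nodes <- nodeIds(net)
  isolated <- setdiff(nodes, nodes[unique(c(i, j))])
  con <- file(path, "w")
  on.exit(close(con))
  for (nd in isolated) writeLines(paste0("#node\t", nd), con)
  if (length(i)) {
    ord <- order(i, j)
    writeLines(sprintf("%s\t%s\t%.10g", nodes[i][ord], nodes[j][ord],
                       w[ord]), con)
  }
}

#' Write a NoN or NoSN bundle directory
#'
#' Layout: `diseases.tsv` (disease similarity edge list), `networks/` with
#' one edge list per molecular network (`<disease>.tsv` for an NoN,
#' `<disease>.center.tsv` / `<disease>.aux<p>.tsv` for an NoSN),
#' `associations.tsv` (`disease_id<TAB>gene_id`), a `manifest.tsv` listing
#' every network file and its role, and optionally `truth.json` with
#' generator ground truth.
#'
#' @param bundle a [NoN-class] or [NoSN-class].
#' @param dir output directory (created).
#' @param associations association table to persist.
#' @param truth optional list written as `truth.json`.
#' @return invisibly, `dir`.
#' @export
writeBundle <- function(bundle, dir, associations = NULL, truth = NULL) {
  dir.create(file.path(dir, "networks"), recursive = TRUE,
             showWarnings = FALSE)
  writeEdgeList(diseaseNetwork(bundle), file.path(dir, "diseases.tsv"))
  manifest <- data.frame(file = character(), disease = character(),
                         role = character(), index = integer())
  if (is(bundle, "NoSN")) {
    for (d in nodeIds(diseaseNetwork(bundle))) {
      f <- file.path("networks", paste0(d, ".center.tsv"))
      writeEdgeList(centerNetworks(bundle)[[d]], file.path(dir, f))
      manifest <- rbind(manifest, data.frame(file = f, disease = d,
                                             role = "center", index = 0L))
      auxs <- auxNetworks(bundle, d)
      for (p in seq_along(auxs)) {
        f <- file.path("networks", paste0(d, ".aux", p, ".tsv"))
        writeEdgeList(auxs[[p]], file.path(dir, f))
        manifest <- rbind(manifest, data.frame(file = f, disease = d,
                                               role = "aux", index = p))
      }
    }
  } else {
    for (d in nodeIds(diseaseNetwork(bundle))) {
      f <- file.path("networks", paste0(d, ".tsv"))
      writeEdgeList(molecularNetworks(bundle)[[d]], file.path(dir, f))
      manifest <- rbind(manifest, data.frame(file = f, disease = d,
                                             role = "molecular", index = 0L))
    }
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (is.null(associations))
    associations <- data.frame(disease = character(), gene = character())
  utils::write.table(associations[, 1:2], file.path(dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a NoN or NoSN bundle directory
#'
#' @param dir directory written by [writeBundle()].
#' @return list with `bundle` (a [NoN-class] or [NoSN-class], seeds built
#'   from the persisted associations) and `associations`.
#' @export
readBundle <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  diseaseNet <- readEdgeList(file.path(dir, "diseases.tsv"))
  assocPath <- file.path(dir, "associations.tsv")
  associations <- if (file.size(assocPath) > 0)
    utils::read.delim(assocPath, header = FALSE,
                      col.names = c("disease", "gene"),
                      stringsAsFactors = FALSE)
  else data.frame(disease = character(), gene = character())
  isStar <- any(manifest$role == "center")
  if (isStar) {
    centers <- list(); auxiliaries <- list()
    for (r in seq_len(nrow(manifest))) {
      net <- readEdgeList(file.path(dir, manifest$file[r]))
      d <- manifest$disease[r]
      if (manifest$role[r] == "center") centers[[d]] <- net
      else auxiliaries[[d]][[manifest$index[r]]] <- net
    }
    bundle <- NoSN(diseaseNet, centers, auxiliaries, associations)
  } else {
    networks <- list()
    for (r in seq_len(nrow(manifest)))
      networks[[manifest$disease[r]]] <-
        readEdgeList(file.path(dir, manifest$file[r]))
    bundle <- NoN(diseaseNet, networks, associations)
  }
  list(bundle = bundle, associations = associations)
}
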