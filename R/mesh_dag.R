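#' Parse name/tree-code records into a disease DAG
#'
#' Builds a disease directed acyclic graph from MeSH-style dotted tree
#' codes (e.g. \code{"C04.588.274"}). Every proper prefix of a code is the
#' code of an ancestor position, so the hierarchy is implied entirely by
#' the codes: no explicit edge list is needed. A disease may own several
#' codes (several positions in the hierarchy); records sharing a name are
#' merged into one disease.
#'
#' @param records a data.frame (or list of length-2 vectors) with columns
#'   \code{name} and \code{code}: one row per (disease, tree code) pair.
#' @return an object of class \code{disease_dag} with components
#'   \describe{
#'     \item{diseases}{named list, disease name -> character vector of codes}
#'     \item{code_index}{named character vector, code -> disease name}
#'   }
#' @examples
#' dag <- parse_tree_code_records(data.frame(
#'   name = c("Neoplasms", "Hepatocellular Carcinoma",
#'            "Hepatocellular Carcinoma"),
#'   code = c("C04", "C04.588.274.623.160", "C04.557.470.200.025.255")))
#' ancestor_distance(dag, "Neoplasms", "Hepatocellular Carcinoma")
#' @export
parse_tree_code_records <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- data.frame(
      name = vapply(records, function(r) as.character(r[[1]]), character(1)),
      code = vapply(records, function(r) as.character(r[[2]]), character(1)),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(records), all(c("name", "code") %in% names(records)))
  if (nrow(records) == 0L) stop("no tree-code records supplied")
  name <- as.character(records$name)
  code <- as.character(records$code)

  bad <- which(!grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", code))
  if (length(bad) > 0L) {
    stop(sprintf("malformed tree code at record %d: '%s' (disease '%s')",
                 bad[1], code[bad[1]], name[bad[1]]))
  }
  dup <- duplicated(code)
  if (any(dup)) {
    d <- code[dup][1]
    owners <- unique(name[code == d])
    if (length(owners) > 1L) {
      stop(sprintf("tree code '%s' is mapped to two diseases: '%s' and '%s'",
                   d, owners[1], owners[2]))
    }
    keep <- !dup
    name <- name[keep]
    code <- code[keep]
  }

  code_index <- stats::setNames(name, code)
  diseases <- lapply(split(code, name), sort)
  structure(list(diseases = diseases, code_index = code_index),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("disease_dag: %d diseases, %d tree codes\n",
              length(x$diseases), length(x$code_index)))
  invisible(x)
}

#' Read a disease tree-code TSV into a DAG
#'
#' Expects two tab-separated columns, \code{disease_name<TAB>tree_code},
#' one row per code; lines starting with \code{#} are comments.
#'
#' @param path path to the TSV file.
#' @return a \code{disease_dag}; see [parse_tree_code_records()].
#' @export
read_tree_codes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("name", "code"),
                          colClasses = "character", quote = "",
                          fill = FALSE, strip.white = TRUE)
  parse_tree_code_records(df)
}

#' Write a DAG back to the tree-code TSV dialect
#'
#' @param dag a \code{disease_dag}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_tree_codes <- function(dag, path) {
  stopifnot(inherits(dag, "disease_dag"))
  df <- data.frame(name = unname(dag$code_index),
                   code = names(dag$code_index),
                   stringsAsFactors = FALSE)
  df <- df[order(df$name, df$code), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read disease records from a MeSH descriptor XML file
#'
#' Extracts \code{DescriptorName/String} and \code{TreeNumber} pairs from a
#' MeSH descriptor XML dump and returns them as the same record stream the
#' TSV reader produces, so either source feeds
#' [parse_tree_code_records()] unchanged.
#'
#' @param path path to a MeSH descriptor XML file.
#' @return data.frame with columns \code{name}, \code{code}.
#' @export
read_mesh_xml <- function(path) {
  doc <- xml2::read_xml(path)
  recs <- xml2::xml_find_all(doc, ".//DescriptorRecord")
  out <- lapply(recs, function(r) {
    nm <- xml2::xml_text(
      xml2::xml_find_first(r, "./DescriptorName/String"))
    tns <- xml2::xml_text(
      xml2::xml_find_all(r, ".//TreeNumberList/TreeNumber"))
    if (length(tns) == 0L) return(NULL)
    data.frame(name = nm, code = tns, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no DescriptorRecord with TreeNumber found in ", path)
  out
}

code_depth <- function(code) {
  lengths(strsplit(code, ".", fixed = TRUE))
}

code_prefixes <- function(code) {
  segs <- strsplit(code, ".", fixed = TRUE)[[1]]
  vapply(seq_along(segs), function(k) paste(segs[seq_len(k)], collapse = "."),
         character(1))
}

assert_in_dag <- function(dag, nm) {
  if (!nm %in% names(dag$diseases)) {
    stop(sprintf("disease '%s' is not in the DAG", nm))
  }
}

#' Shortest ancestor distance between two diseases
#'
#' The distance is the minimum, over every tree code of the descendant and
#' every prefix of that code owned by the candidate ancestor, of the depth
#' difference (number of child-to-parent edges). Both diseases may own
#' several codes; the global minimum over all (code, prefix) matches is
#' taken. A disease is at distance 0 from itself.
#'
#' @param dag a \code{disease_dag}.
#' @param ancestor,descendant disease names present in the DAG.
#' @return a non-negative integer, or \code{NA_integer_} when
#'   \code{ancestor} owns no prefix of any code of \code{descendant}.
#' @export
ancestor_distance <- function(dag, ancestor, descendant) {
  stopifnot(inherits(dag, "disease_dag"))
  assert_in_dag(dag, ancestor)
  assert_in_dag(dag, descendant)
  if (identical(ancestor, descendant)) return(0L)
  best <- NA_integer_
  for (code in dag$diseases[[descendant]]) {
    prefs <- code_prefixes(code)
    d <- length(prefs)
    owned <- prefs[prefs %in% names(dag$code_index)]
    owned <- owned[dag$code_index[owned] == ancestor]
    if (length(owned) > 0L) {
      delta <- d - code_depth(owned)      # depth difference per matching prefix
      best <- min(best, min(delta), na.rm = TRUE)
    }
  }
  as.integer(best)
}

#' Ancestor-distance feature vector of a disease
#'
#' Encodes a disease \eqn{d} as a sparse vector over the ontology: the
#' entry for an ancestor \eqn{a} at shortest distance \eqn{\delta} is
#' \eqn{1/(\delta+1)}; the disease's own entry (\eqn{\delta = 0}) is 1;
#' non-ancestors are absent (zero). More specific ancestors therefore get
#' larger weights.
#'
#' @param dag a \code{disease_dag}.
#' @param disease a disease name present in the DAG.
#' @return an object of class \code{feature_vector}: a named numeric vector
#'   of weights in (0, 1] over ancestor names, with attributes
#'   \code{disease} (the name) and \code{dimension} (number of diseases in
#'   the DAG).
#' @export
feature_vector <- function(dag, disease) {
  stopifnot(inherits(dag, "disease_dag"))
  assert_in_dag(dag, disease)
  delta <- new.env(parent = emptyenv())
  for (code in dag$diseases[[disease]]) {
    prefs <- code_prefixes(code)
    d <- length(prefs)
    hit <- prefs %in% names(dag$code_index)
    if (!any(hit)) next
    owners <- dag$code_index[prefs[hit]]
    dist <- d - code_depth(prefs[hit])
    for (k in seq_along(owners)) {
      nm <- owners[[k]]
      cur <- get0(nm, envir = delta, ifnotfound = Inf)
      if (dist[k] < cur) assign(nm, dist[k], envir = delta)
    }
  }
  assign(disease, 0, envir = delta)   # delta = 0 for the disease itself
  nms <- ls(delta)
  w <- vapply(nms, function(nm) 1 / (get(nm, envir = delta) + 1), numeric(1))
  structure(w[order(names(w))],
            disease = disease,
            dimension = length(dag$diseases),
            class = "feature_vector")
}
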