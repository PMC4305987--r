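#' @importFrom stats median rgamma runif setNames quantile
#' @importFrom utils head tail write.table read.delim
NULL

.ASPECT_NAMESPACE <- c(MF = "molecular_function",
                       BP = "biological_process",
                       CC = "cellular_component")
.ASPECT_GAF <- c(MF = "F", BP = "P", CC = "C")

#' Construct an ontology DAG object
#'
#' Internal constructor used by [parse_obo()] and the fixture generator.
#' Validates acyclicity and the single-root requirement for the aspect.
#'
#' @param terms character vector of term identifiers.
#' @param edges data frame with columns `child`, `parent`, `relation`
#'   (each relation one of `"is_a"`, `"part_of"`).
#' @param aspect one of `"MF"`, `"BP"`, `"CC"`.
#' @param alt_id optional named character vector mapping secondary term
#'   identifiers to their primary identifier.
#' @return an object of class `ontology_dag`.
#' @keywords internal
new_ontology_dag <- function(terms, edges, aspect, alt_id = character()) {
  aspect <- match.arg(aspect, names(.ASPECT_NAMESPACE))
  terms <- sort(unique(terms))
  stopifnot(is.data.frame(edges),
            all(c("child", "parent", "relation") %in% names(edges)))
  edges <- edges[order(edges$child, edges$parent, edges$relation), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges)) {
    bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
    if (length(bad_rel)) {
      stop("unsupported relation(s): ", paste(bad_rel, collapse = ", "))
    }
    missing <- setdiff(unique(c(edges$child, edges$parent)), terms)
    if (length(missing)) {
      stop("edges reference unknown term(s): ",
           paste(head(missing, 5), collapse = ", "))
    }
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       directed = TRUE,
                                       vertices = terms)
    if (!igraph::is_dag(g)) {
      stop("ontology structure contains a cycle; not a DAG")
    }
  }
  has_parent <- terms %in% edges$child
  roots <- terms[!has_parent]
  if (length(roots) != 1L) {
    stop("expected exactly one root for aspect ", aspect, ", found ",
         length(roots),
         if (length(roots)) paste0(": ", paste(head(roots, 5), collapse = ", "))
         else "")
  }
  parent_map <- split(seq_len(nrow(edges)), factor(edges$child, levels = terms))
  child_map <- split(seq_len(nrow(edges)), factor(edges$parent, levels = terms))
  structure(
    list(terms = terms,
         edges = edges,
         aspect = aspect,
         root = roots,
         alt_id = alt_id,
         parent_idx = parent_map,
         child_idx = child_map,
         cache = new.env(parent = emptyenv())),
    class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> aspect=%s terms=%d edges=%d root=%s\n",
              x$aspect, length(x$terms), nrow(x$edges), x$root))
  invisible(x)
}

#' Parse an OBO ontology file for one aspect
#'
#' Reads an OBO 1.2/1.4 flat file and returns the term DAG restricted to one
#' GO aspect. Only `is_a` and `part_of` relations are retained; obsolete
#' terms are dropped and their stanzas ignored; `alt_id` lines are recorded
#' so annotation readers can resolve secondary identifiers. Edges pointing
#' outside the aspect are discarded.
#'
#' @param path path to an OBO file.
#' @param aspect one of `"MF"`, `"BP"`, `"CC"`.
#' @return an `ontology_dag` with fields `terms`, `edges`, `aspect`, `root`.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "",
#'   "[Term]", "id: GO:0000001", "namespace: molecular_function", "",
#'   "[Term]", "id: GO:0000002", "namespace: molecular_function",
#'   "is_a: GO:0000001"), obo)
#' dag <- parse_obo(obo, "MF")
#' dag$root
#' @export
parse_obo <- function(path, aspect = c("MF", "BP", "CC")) {
  aspect <- match.arg(aspect)
  ns <- .ASPECT_NAMESPACE[[aspect]]
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  if (!length(stanza_starts)) stop("no [Term] stanzas found in ", path)
  stanza_ends <- c(stanza_starts[-1] - 1L, length(lines))
  terms <- character()
  alt_from <- character(); alt_to <- character()
  e_child <- character(); e_parent <- character(); e_rel <- character()
  for (k in seq_along(stanza_starts)) {
    block <- lines[stanza_starts[k]:stanza_ends[k]]
    block <- block[nzchar(block) & block != "[Term]"]
    get_vals <- function(key) {
      hits <- block[startsWith(block, paste0(key, ": "))]
      sub("\\s*(!.*)?$", "", substring(hits, nchar(key) + 3L))
    }
    id <- get_vals("id")
    if (length(id) != 1L) next
    if (any(grepl("^true", get_vals("is_obsolete")))) next
    if (length(get_vals("namespace")) && get_vals("namespace") != ns) next
    if (!length(get_vals("namespace"))) next
    terms <- c(terms, id)
    alts <- get_vals("alt_id")
    if (length(alts)) {
      alt_from <- c(alt_from, alts)
      alt_to <- c(alt_to, rep(id, length(alts)))
    }
    isa <- get_vals("is_a")
    if (length(isa)) {
      e_child <- c(e_child, rep(id, length(isa)))
      e_parent <- c(e_parent, isa)
      e_rel <- c(e_rel, rep("is_a", length(isa)))
    }
    rels <- get_vals("relationship")
    po <- grep("^part_of ", rels, value = TRUE)
    if (length(po)) {
      tgt <- sub("^part_of\\s+", "", po)
      e_child <- c(e_child, rep(id, length(tgt)))
      e_parent <- c(e_parent, tgt)
      e_rel <- c(e_rel, rep("part_of", length(tgt)))
    }
  }
  terms <- unique(terms)
  keep <- e_child %in% terms & e_parent %in% terms
  edges <- data.frame(child = e_child[keep], parent = e_parent[keep],
                      relation = e_rel[keep], stringsAsFactors = FALSE)
  alt <- setNames(alt_to, alt_from)
  alt <- alt[alt %in% terms]
  new_ontology_dag(terms, edges, aspect, alt_id = alt)
}

#' Write an ontology DAG as an OBO file
#'
#' Emits a minimal, deterministic OBO 1.2 serialization (terms sorted by
#' identifier, edge lines sorted) so that fixture ontologies round-trip
#' bit-identically through [parse_obo()].
#'
#' @param dag an `ontology_dag`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  ns <- .ASPECT_NAMESPACE[[dag$aspect]]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2",
               "ontology: synthetic-fixture"), con)
  for (t in dag$terms) {
    idx <- dag$parent_idx[[t]]
    writeLines(c("", "[Term]", paste0("id: ", t), paste0("name: ", t),
                 paste0("namespace: ", ns)), con)
    if (length(idx)) {
      e <- dag$edges[idx, , drop = FALSE]
      e <- e[order(e$relation, e$parent), , drop = FALSE]
      for (i in seq_len(nrow(e))) {
        if (e$relation[i] == "is_a") {
          writeLines(paste0("is_a: ", e$parent[i]), con)
        } else {
          writeLines(paste0("relationship: part_of ", e$parent[i]), con)
        }
      }
    }
  }
  invisible(path)
}

#' Ancestors of a term (reflexive transitive closure)
#'
#' Closure over `is_a` and `part_of` edges, including the term itself.
#' Results are memoized on the DAG object.
#'
#' @param dag an `ontology_dag`.
#' @param term a term identifier present in `dag`.
#' @return character vector of term identifiers (sorted).
#' @export
ancestors <- function(dag, term) {
  if (!term %in% dag$terms) stop("unknown term: ", term)
  key <- paste0("anc.", term)
  hit <- dag$cache[[key]]
  if (!is.null(hit)) return(hit)
  seen <- character()
  stack <- term
  while (length(stack)) {
    t <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (t %in% seen) next
    seen <- c(seen, t)
    idx <- dag$parent_idx[[t]]
    if (length(idx)) stack <- c(stack, dag$edges$parent[idx])
  }
  out <- sort(seen)
  assign(key, out, envir = dag$cache)
  out
}

#' Descendants of a term (reflexive transitive closure)
#'
#' @inheritParams ancestors
#' @return character vector of term identifiers (sorted).
#' @export
descendants <- function(dag, term) {
  if (!term %in% dag$terms) stop("unknown term: ", term)
  key <- paste0("desc.", term)
  hit <- dag$cache[[key]]
  if (!is.null(hit)) return(hit)
  seen <- character()
  stack <- term
  while (length(stack)) {
    t <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (t %in% seen) next
    seen <- c(seen, t)
    idx <- dag$child_idx[[t]]
    if (length(idx)) stack <- c(stack, dag$edges$child[idx])
  }
  out <- sort(seen)
  assign(key, out, envir = dag$cache)
  out
}

#' Leaf terms of the DAG
#'
#' @param dag an `ontology_dag`.
#' @return character vector of terms with no children.
#' @export
leaf_terms <- function(dag) {
  dag$terms[vapply(dag$child_idx[dag$terms], length, 1L) == 0L]
}

#' Construct an annotation corpus
#'
#' @param direct named list: gene id -> character vector of directly
#'   annotated term identifiers.
#' @param dag the companion `ontology_dag`; used to validate terms and to
#'   compute the ancestor closure of every gene's annotation set.
#' @return an `annotation_corpus` with fields `direct`, `closed`
#'   (ancestor-closed term sets) and `genes`.
#' @export
annotation_corpus <- function(direct, dag) {
  stopifnot(is.list(direct), length(direct) > 0L)
  genes <- names(direct)
  if (is.null(genes) || any(!nzchar(genes))) stop("genes must be named")
  direct <- lapply(direct, function(ts) sort(unique(as.character(ts))))
  unknown <- setdiff(unique(unlist(direct)), dag$terms)
  if (length(unknown)) {
    stop("annotation to term(s) absent from the DAG: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  closed <- lapply(direct, function(ts) {
    sort(unique(unlist(lapply(ts, ancestors, dag = dag))))
  })
  structure(list(direct = direct, closed = closed, genes = genes),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("<annotation_corpus> genes=%d mean direct terms=%.1f\n",
              length(x$genes), mean(lengths(x$direct))))
  invisible(x)
}

#' Parse a GAF 2.x annotation file
#'
#' Reads a tab-separated Gene Association File (comment lines start with
#' `!`). Rows are kept when the aspect column matches the DAG's aspect, the
#' qualifier carries no `NOT`, and (optionally) the evidence code is in the
#' allowlist. Secondary term identifiers are resolved through the DAG's
#' `alt_id` map. The gene identifier is column 2 (DB Object ID).
#'
#' @param path path to a GAF file.
#' @param dag `ontology_dag` for the target aspect.
#' @param unknown_term `"skip"` (warn and drop rows annotating terms absent
#'   from the DAG) or `"error"`.
#' @param evidence_allow optional character vector of evidence codes to
#'   retain; `NULL` keeps all.
#' @return an `annotation_corpus`.
#' @export
parse_gaf <- function(path, dag, unknown_term = c("skip", "error"),
                      evidence_allow = NULL) {
  unknown_term <- match.arg(unknown_term)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) stop("no annotation rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 9L
  if (any(short)) stop("malformed GAF row(s): fewer than 9 columns")
  gene <- vapply(fields, `[[`, "", 2L)
  qual <- vapply(fields, `[[`, "", 4L)
  term <- vapply(fields, `[[`, "", 5L)
  evid <- vapply(fields, `[[`, "", 7L)
  asp <- vapply(fields, `[[`, "", 9L)
  keep <- asp == .ASPECT_GAF[[dag$aspect]]
  keep <- keep & !vapply(strsplit(qual, "|", fixed = TRUE),
                         function(q) "NOT" %in% q, TRUE)
  if (!is.null(evidence_allow)) keep <- keep & evid %in% evidence_allow
  gene <- gene[keep]; term <- term[keep]
  resolved <- ifelse(term %in% names(dag$alt_id), dag$alt_id[term], term)
  known <- resolved %in% dag$terms
  if (any(!known)) {
    msg <- paste0("annotation(s) to unknown term(s): ",
                  paste(head(unique(resolved[!known]), 5), collapse = ", "))
    if (unknown_term == "error") stop(msg)
    warning(msg, " (skipped)")
  }
  gene <- gene[known]; resolved <- resolved[known]
  if (!length(gene)) stop("no usable annotations for aspect ", dag$aspect)
  annotation_corpus(split(resolved, gene), dag)
}

#' Write annotations as a GAF 2.2 file
#'
#' Deterministic serialization of direct annotations (genes and terms
#' sorted), used by the fixture generator.
#'
#' @param direct named list gene -> term identifiers.
#' @param path output file path.
#' @param aspect one of `"MF"`, `"BP"`, `"CC"`.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(direct, path, aspect = "MF") {
  aspect <- match.arg(aspect, names(.ASPECT_GAF))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  for (g in sort(names(direct))) {
    for (t in sort(unique(direct[[g]]))) {
      writeLines(paste(c("FIX", g, g, "enables", t, "FIX:0000001", "IEA",
                         "", .ASPECT_GAF[[aspect]], g, "", "protein",
                         "taxon:0", "20140101", "FIX", "", ""),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Information content of ontology terms from annotation frequency
#'
#' The annotation probability of a term is the fraction of annotated genes
#' whose ancestor-closed annotation set contains the term; its information
#' content is the negative natural logarithm of that probability. The root
#' therefore has IC 0, and IC never decreases when moving from a parent to
#' a child. Terms annotating no gene carry `NA` IC and are excluded from
#' most-informative-common-ancestor candidacy downstream.
#'
#' @param dag an `ontology_dag`.
#' @param corpus an `annotation_corpus` over `dag`.
#' @return an `ic_table`: list with named numeric vectors `p` and `ic` over
#'   all DAG terms, plus `n_genes`.
#' @export
compute_ic <- function(dag, corpus) {
  if (!length(corpus$genes)) stop("empty annotation corpus")
  counts <- table(factor(unlist(corpus$closed, use.names = FALSE),
                         levels = dag$terms))
  p <- as.numeric(counts) / length(corpus$genes)
  names(p) <- dag$terms
  ic <- ifelse(p > 0, -log(p), NA_real_)
  names(ic) <- dag$terms
  structure(list(p = p, ic = ic, n_genes = length(corpus$genes)),
            class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat(sprintf("<ic_table> terms=%d annotated=%d max ic=%.3f\n",
              length(x$ic), sum(!is.na(x$ic)), max(x$ic, na.rm = TRUE)))
  invisible(x)
}
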