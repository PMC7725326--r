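#' @name biopax
#' @title BioPAX Level 3 pathway extraction and presence/absence annotation
#' @description
#' Pathways travel as BioPAX Level 3 OWL/XML documents in which the pathway
#' is a `bp:Pathway` element and each enzyme a `bp:ProteinReference`
#' element. Presence or absence inferred for a tree node is written back as
#' a structured custom comment — a `bp:comment` sub-element whose text is
#' exactly `$$custom comment$$:present` or `$$custom comment$$:absent`
#' (prefix, colon, state; no whitespace) — because BioPAX L3 itself has no
#' presence flag. Everything the annotator does not touch is preserved.
NULL

BP_NS <- "http://www.biopax.org/release/biopax-level3.owl#"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
XSD_STRING <- "http://www.w3.org/2001/XMLSchema#string"
FLAG_PREFIX <- "$$custom comment$$:"

biopax_ns <- function() c(bp = BP_NS, rdf = RDF_NS)

#' Read a BioPAX Level 3 document
#'
#' @param path Path to an OWL/XML file.
#' @return An `xml2` document of class `biopax_doc`.
#' @export
read_biopax <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed BioPAX XML: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  class(doc) <- c("biopax_doc", class(doc))
  doc
}

#' @rdname read_biopax
#' @param doc A `biopax_doc`.
#' @export
write_biopax <- function(doc, path) {
  xml2::write_xml(doc, path)
  invisible(path)
}

# element identifier: rdf:about if set, else rdf:ID
bp_id <- function(node) {
  for (a in c("rdf:about", "about", "rdf:ID", "ID")) {
    id <- xml2::xml_attr(node, a)
    if (!is.na(id)) return(id)
  }
  NA_character_
}

bp_text_child <- function(node, name) {
  child <- xml2::xml_find_first(node, paste0("./bp:", name), biopax_ns())
  if (inherits(child, "xml_missing")) NA_character_ else
    xml2::xml_text(child)
}

#' Extract a pathway definition and protein sequences from BioPAX
#'
#' Collects the document's `bp:Pathway` identifier/name and the identifiers
#' of all `bp:ProteinReference` elements (document order) into a
#' [pathway_definition()]. Amino-acid sequences embedded as `bp:sequence`
#' sub-elements are returned verbatim; references without one are resolved
#' against an optional local FASTA file (never over the network) and
#' reported as `NA` when still missing.
#'
#' @param doc A `biopax_doc` (see [read_biopax()]).
#' @param fasta Optional path to a local FASTA file of protein sequences
#'   keyed by the ProteinReference identifiers (requires the Biostrings
#'   package).
#' @return List with `pathway` (a [pathway_definition()]; empty enzyme
#'   lists raise a warning and return a zero-enzyme placeholder) and
#'   `sequences` (named character vector, `NA` for unresolved).
#' @export
extract_proteins <- function(doc, fasta = NULL) {
  stopifnot(inherits(doc, "biopax_doc"))
  ns <- biopax_ns()
  pw <- xml2::xml_find_first(doc, ".//bp:Pathway", ns)
  if (inherits(pw, "xml_missing")) {
    stop("no bp:Pathway element in document", call. = FALSE)
  }
  pw_id <- bp_id(pw)
  pw_name <- bp_text_child(pw, "displayName")
  if (is.na(pw_name)) pw_name <- bp_text_child(pw, "standardName")
  if (is.na(pw_name)) pw_name <- pw_id
  refs <- xml2::xml_find_all(doc, ".//bp:ProteinReference", ns)
  ids <- vapply(refs, bp_id, "")
  seqs <- vapply(refs, bp_text_child, "", name = "sequence")
  names(seqs) <- ids
  if (!is.null(fasta) && any(is.na(seqs))) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("local FASTA resolution requires the Biostrings package",
           call. = FALSE)
    }
    aa <- Biostrings::readAAStringSet(fasta)
    # FASTA headers may carry descriptions after the ID token
    names(aa) <- vapply(strsplit(names(aa), "\\s+"), `[[`, "", 1L)
    hit <- is.na(seqs) & names(seqs) %in% names(aa)
    seqs[hit] <- as.character(aa[names(seqs)[hit]])
  }
  if (!length(ids)) {
    warning("pathway '", pw_id, "' declares no ProteinReference elements; ",
            "downstream profile construction requires >= 1 enzyme",
            call. = FALSE)
    pathway <- structure(list(pathway_id = pw_id, name = pw_name,
                              enzyme_ids = character(0),
                              source_genome = NA_character_),
                         class = "pathway_definition")
  } else {
    pathway <- pathway_definition(pw_id, ids, name = pw_name)
  }
  list(pathway = pathway, sequences = seqs)
}

# remove any presence/absence flags already on the element, then insert one
set_flag <- function(node, state) {
  old <- xml2::xml_find_all(node, "./bp:comment", biopax_ns())
  old <- old[startsWith(xml2::xml_text(old), FLAG_PREFIX)]
  xml2::xml_remove(old)
  cm <- xml2::xml_add_child(node, "bp:comment",
                            paste0(FLAG_PREFIX, state))
  xml2::xml_set_attr(cm, "rdf:datatype", XSD_STRING)
  invisible(node)
}

#' Annotate pathway and protein presence/absence in a BioPAX document
#'
#' Inserts (or replaces — annotation is idempotent by replacement) one
#' presence/absence custom comment under the `bp:Pathway` element and under
#' each named `bp:ProteinReference`. The comment text matches
#' `^\\$\\$custom comment\\$\\$:(present|absent)$` exactly and carries the
#' XML-Schema string datatype.
#'
#' @param doc A `biopax_doc`; modified in place (xml2 documents are
#'   reference semantics) and returned.
#' @param pathway_state `"present"` or `"absent"` for the pathway element.
#' @param protein_states Named character vector of `"present"`/`"absent"`
#'   keyed by ProteinReference identifiers; may be empty.
#' @return The annotated `biopax_doc`.
#' @export
annotate_states <- function(doc, pathway_state,
                            protein_states = character(0)) {
  stopifnot(inherits(doc, "biopax_doc"))
  states <- c(pathway_state, unname(protein_states))
  if (!all(states %in% c("present", "absent"))) {
    stop("states must be 'present' or 'absent'", call. = FALSE)
  }
  ns <- biopax_ns()
  pw <- xml2::xml_find_first(doc, ".//bp:Pathway", ns)
  if (inherits(pw, "xml_missing")) {
    stop("no bp:Pathway element in document", call. = FALSE)
  }
  set_flag(pw, pathway_state)
  if (length(protein_states)) {
    refs <- xml2::xml_find_all(doc, ".//bp:ProteinReference", ns)
    ids <- vapply(refs, bp_id, "")
    unknown <- setdiff(names(protein_states), ids)
    if (length(unknown)) {
      stop("unknown ProteinReference ID(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (pid in names(protein_states)) {
      set_flag(refs[[match(pid, ids)]], protein_states[[pid]])
    }
  }
  doc
}

#' Remove all presence/absence annotations
#'
#' Strips every custom comment carrying the presence/absence prefix,
#' recovering a document canonically equal to the pre-annotation input.
#'
#' @param doc A `biopax_doc`; modified in place and returned.
#' @export
strip_annotations <- function(doc) {
  stopifnot(inherits(doc, "biopax_doc"))
  cms <- xml2::xml_find_all(doc, ".//bp:comment", biopax_ns())
  cms <- cms[startsWith(xml2::xml_text(cms), FLAG_PREFIX)]
  xml2::xml_remove(cms)
  doc
}

# whitespace-insensitive canonical form for round-trip comparison
biopax_canonical <- function(doc) {
  as.character(xml2::read_xml(as.character(doc), options = "NOBLANKS"))
}

#' Write one annotated BioPAX file per tree node
#'
#' For every node of a fitted reconstruction, emits a copy of the template
#' document annotated with that node's pathway state (proteins inherit the
#' pathway state; per-protein states at a node would require per-enzyme
#' reconstructions, which the pathway-level fit does not carry).
#'
#' @param template Path to the BioPAX L3 template document.
#' @param fit A [pathtrace()] object.
#' @param out_dir Output directory; files are named
#'   `<node>.owl`.
#' @return Invisibly, the written file paths.
#' @export
annotate_per_node <- function(template, fit, out_dir) {
  stopifnot(inherits(fit, "pathtrace"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (node in names(fit$states)) {
    doc <- read_biopax(template)
    state <- tolower(fit$states[[node]])
    refs <- xml2::xml_find_all(doc, ".//bp:ProteinReference", biopax_ns())
    ids <- vapply(refs, bp_id, "")
    annotate_states(doc, state,
                    stats::setNames(rep(state, length(ids)), ids))
    fp <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9._-]", "_", node),
                                    ".owl"))
    write_biopax(doc, fp)
    paths <- c(paths, fp)
  }
  invisible(paths)
}
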