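# Random rooted multifurcating topologies and small in-memory fixtures,
# generated in code so no binary data ships with the package.

random_newick_clade <- function(labels) {
  if (length(labels) == 1L) return(labels)
  k <- if (length(labels) == 2L) 2L else
    sample(2:min(length(labels), 4L), 1L)
  grp <- sample(rep(seq_len(k), length.out = length(labels)))
  parts <- vapply(seq_len(k), function(g)
    random_newick_clade(labels[grp == g]), "")
  paste0("(", paste(parts, collapse = ","), ")")
}

random_topology <- function(n_leaves, labels = paste0("t", seq_len(n_leaves))) {
  parse_newick(paste0(random_newick_clade(labels), ";"))
}

random_leaf_states <- function(tree, p = 0.5) {
  stats::setNames(stats::rbinom(length(tree$tip.label), 1L, p),
                  tree$tip.label)
}

# minimal BioPAX L3 document with one Pathway and n ProteinReference
# elements, built as text
make_biopax_doc <- function(n_proteins = 3L, with_sequence = FALSE,
                            with_pathway = TRUE) {
  refs <- vapply(seq_len(n_proteins), function(i) {
    seqel <- if (with_sequence) {
      paste0("<bp:sequence rdf:datatype=\"http://www.w3.org/2001/XMLSchema#string\">MSEQ",
             i, "</bp:sequence>")
    } else ""
    paste0("<bp:ProteinReference rdf:about=\"prot", i, "\">",
           "<bp:displayName>enzyme ", i, "</bp:displayName>", seqel,
           "</bp:ProteinReference>")
  }, "")
  pw <- if (with_pathway) {
    "<bp:Pathway rdf:about=\"pwy1\"><bp:displayName>toy pathway</bp:displayName></bp:Pathway>"
  } else ""
  txt <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
    " xmlns:bp=\"http://www.biopax.org/release/biopax-level3.owl#\">",
    pw, paste(refs, collapse = ""), "</rdf:RDF>")
  path <- tempfile(fileext = ".owl")
  writeLines(txt, path)
  path
}
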