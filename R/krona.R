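#' Write a Krona-compatible XML summary of classification results
#'
#' Aggregates classified contigs per accepted lineage into the nested
#' node/count structure Krona consumes; leaf counts sum to the number of
#' classified contigs. Unclassified contigs are grouped under an
#' `"Unclassified"` top-level node.
#'
#' @param results classification results from [classify_batch()].
#' @param path output XML file.
#' @return `path`, invisibly.
#' @export
write_krona_xml <- function(results, path) {
  res <- data.table::as.data.table(results)
  doc <- xml2::xml_new_root("krona")
  attrs <- xml2::xml_add_child(doc, "attributes", magnitude = "count")
  xml2::xml_add_child(attrs, "attribute", "count", display = "Contigs")
  ds <- xml2::xml_add_child(doc, "datasets")
  xml2::xml_add_child(ds, "dataset", "taxaai")

  add_count <- function(node, n) {
    cn <- xml2::xml_add_child(node, "count")
    xml2::xml_add_child(cn, "val", as.character(n))
  }
  root <- xml2::xml_add_child(doc, "node", name = "Root")
  add_count(root, nrow(res))
  if (nrow(res)) {
    res[, `:=`(p = data.table::fifelse(is.na(phylum), "Unclassified", phylum),
               g = data.table::fifelse(is.na(genus), "", genus),
               s = data.table::fifelse(is.na(species), "", species))]
    for (pv in sort(unique(res$p))) {
      subp <- res[p == pv]
      np <- xml2::xml_add_child(root, "node", name = pv)
      add_count(np, nrow(subp))
      for (gv in sort(unique(subp[nzchar(g)]$g))) {
        subg <- subp[g == gv]
        ng <- xml2::xml_add_child(np, "node", name = gv)
        add_count(ng, nrow(subg))
        for (sv in sort(unique(subg[nzchar(s)]$s))) {
          ns <- xml2::xml_add_child(ng, "node", name = sv)
          add_count(ns, nrow(subg[s == sv]))
        }
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
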