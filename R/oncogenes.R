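#' Glioma proto-oncogene set
#'
#' Loads the packaged set of 29 proto-oncogenes implicated in glioma
#' formation: 23 genes annotated for glioma (including glioblastoma,
#' astrocytoma and oligodendroglioma) in COSMIC Cancer Gene Census-style
#' curation, plus six genes listed there under other tumour types but
#' independently implicated in gliomagenesis (KRAS, MYC, CDKN2A(p16),
#' CDKN2A(p14), CTNNB1(beta-catenin), ERBB2(HER2)). The 23 glioma-tagged
#' symbols in the packaged file are a synthetic reconstruction assembled
#' from well-established census annotations (the original supplementary
#' listing is not redistributable); the set size and the six named
#' additions are enforced as invariants, and the size is what the model
#' consumes (`n_onco = 29`).
#'
#' @param path Optional path to an alternative gene-set file with
#'   columns `symbol, source`; defaults to the packaged fixture.
#' @return A tibble with columns `symbol` and `source`
#'   (`"cosmic-glioma"` or `"other-tumour-types-addition"`), 29 rows.
#' @examples
#' genes <- load_oncogene_set()
#' nrow(genes)  # 29, the default n_onco of mutation_params()
#' @export
load_oncogene_set <- function(path = NULL) {
  path <- path %||% system.file("extdata", "glioma_oncogenes_synthetic.csv",
                                package = "nscglioma", mustWork = TRUE)
  genes <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (!all(c("symbol", "source") %in% names(genes))) {
    abort("oncogene set integrity error: expected columns `symbol`, `source`.")
  }
  if (anyDuplicated(genes$symbol)) {
    abort(sprintf("oncogene set integrity error: duplicate symbol \"%s\".",
                  genes$symbol[duplicated(genes$symbol)][1]))
  }
  if (nrow(genes) != 29L) {
    abort(sprintf(
      "oncogene set integrity error: expected 29 unique genes, found %d.",
      nrow(genes)))
  }
  additions <- c("KRAS", "MYC", "CDKN2A(p16)", "CDKN2A(p14)",
                 "CTNNB1(beta-catenin)", "ERBB2(HER2)")
  tagged <- genes$symbol[genes$source == "other-tumour-types-addition"]
  if (!setequal(tagged, additions)) {
    abort("oncogene set integrity error: the six other-tumour-type additions are missing or mistagged.")
  }
  as_tibble(genes)
}
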