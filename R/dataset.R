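#' Packaged theropod femur/projection dataset
#'
#' Comparative data for 56 theropod species: femur length in cm (a
#' standard body-size/mass proxy in bipedal non-avian theropods) and a
#' binary code for metaplastic projections on the dorsal neural spines
#' (1 = present, 0 = absent). Rows whose femur length was an estimate in
#' the original description (*Baryonyx*, *Buitreraptor*) carry
#' `femur_estimated = TRUE`.
#'
#' Character-coding vocabulary applied when the table was assembled
#' (specimen-level judgments are outside this package's scope; the rules
#' are shipped as documentation of what the codes mean):
#' \itemize{
#'   \item projections spanning the full height and apex of the spine, or
#'     projecting beyond its anterior/posterior margins: coded 1;
#'   \item projections confined to caudal vertebrae: coded 0;
#'   \item rounded lateral flaring of the spine apex: coded 0;
#'   \item periosteal "hook-like" ligament attachments (compsognathid-style)
#'     and visible scarring that does not project beyond the margins: coded 0.
#' }
#'
#' @return a `trait_table` data.frame with columns taxon, femur_cm,
#'   projections, femur_estimated.
#' @export
theropod_traits <- function() {
  path <- system.file("extdata", "theropod_traits.tsv", package = "spinetrait",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .traits_md5)) {
    stop("packaged trait table failed its checksum (expected ", .traits_md5,
         ", got ", sum, "): installation is corrupted", call. = FALSE)
  }
  tab <- utils::read.delim(path, colClasses = c("character", "numeric",
                                                "integer", "integer"))
  tab$femur_estimated <- as.logical(tab$femur_estimated)
  validate_trait_table(tab)
}

# md5 of inst/extdata/theropod_traits.tsv, fixed at packaging time
.traits_md5 <- "4895598ada763f5135225ea1fd43141e"

#' Read and validate a trait table
#'
#' Expects a delimited text file with a header. Validation enforces the
#' coding contract: unique taxa, strictly positive femur lengths, and a
#' strictly binary projection code. Every violation is reported with the
#' offending row numbers.
#'
#' @param path file path.
#' @param sep field separator; default tab, use "," for CSV.
#' @param col_taxon,col_femur,col_projections column names in the file.
#' @return a validated `trait_table` data.frame.
#' @export
read_trait_table <- function(path, sep = "\t", col_taxon = "taxon",
                             col_femur = "femur_cm",
                             col_projections = "projections") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(col_taxon, col_femur, col_projections)
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tab <- data.frame(taxon = as.character(raw[[col_taxon]]),
                    femur_cm = suppressWarnings(as.numeric(raw[[col_femur]])),
                    projections = suppressWarnings(
                      as.numeric(raw[[col_projections]])),
                    femur_estimated = if ("femur_estimated" %in% names(raw)) {
                      as.logical(raw$femur_estimated)
                    } else FALSE,
                    stringsAsFactors = FALSE)
  validate_trait_table(tab)
}

validate_trait_table <- function(tab) {
  probs <- character()
  dup <- which(duplicated(tab$taxon))
  if (length(dup)) {
    probs <- c(probs, paste0("duplicate taxon at row(s) ",
                             paste(dup, collapse = ", ")))
  }
  bad_f <- which(!is.finite(tab$femur_cm) | tab$femur_cm <= 0)
  if (length(bad_f)) {
    probs <- c(probs, paste0("non-positive femur length at row(s) ",
                             paste(bad_f, collapse = ", ")))
  }
  bad_p <- which(!(tab$projections %in% c(0, 1)))
  if (length(bad_p)) {
    probs <- c(probs, paste0("projection code not in {0,1} at row(s) ",
                             paste(bad_p, collapse = ", ")))
  }
  if (length(probs)) {
    stop("invalid trait table:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  }
  tab$projections <- as.integer(tab$projections)
  class(tab) <- c("trait_table", "data.frame")
  tab
}

#' Natural-log femur length response vector
#'
#' @param tab a `trait_table`.
#' @return named numeric vector, ln(femur length in cm), in table order.
#' @export
ln_femur <- function(tab) {
  stopifnot(inherits(tab, "trait_table"))
  stats::setNames(log(tab$femur_cm), tab$taxon)
}

#' Packaged stand-in phylogeny for the 56 study taxa
#'
#' The original analysis tree (pruned from a larger dinosaur phylogeny)
#' is not publicly printed, so the package ships a SYNTHETIC stand-in: a
#' consensus-style cladogram of the 56 taxa assembled from widely
#' accepted theropod interrelationships, given Grafen branch lengths
#' (node height proportional to clade size, total depth 1). It makes the
#' full pipeline runnable end to end, but posterior quantities computed
#' on it are illustrative only — analyses aimed at the original results
#' must supply the original tree via [read_tree()].
#'
#' @return a `phylo` object with 56 tips.
#' @export
theropod_tree_standin <- function() {
  path <- system.file("extdata", "theropod_tree_standin.nwk",
                      package = "spinetrait", mustWork = TRUE)
  read_tree(file = path)
}
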