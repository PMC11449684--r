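#' Source composition of the public brain-MRI collection
#'
#' Per-source image counts of the open four-class brain-MRI dataset the
#' package targets (an aggregation of the figshare, SARTAJ and Br35H
#' collections), as shipped in `inst/extdata/brain_mri_source_counts.csv`.
#'
#' @return Data frame with columns `class`, `source`, `images`.
#' @export
brain_mri_counts <- function() {
  read.csv(system.file("extdata", "brain_mri_source_counts.csv",
                       package = "actsign"))
}

#' Tally the dataset composition against its published totals
#'
#' Sums the per-source counts for each class and overall, and compares
#' them with the totals the dataset documentation reports (1621 glioma,
#' 1645 meningioma, 1757 pituitary, 2000 no-tumor; 7023 overall).
#'
#' @return List with `per_class` (data frame `class`, `computed`,
#'   `published`, `match`), `total_computed`, `total_published`, and
#'   `total_match`.
#' @export
dataset_tally <- function() {
  counts <- brain_mri_counts()
  published <- c(glioma = 1621, meningioma = 1645, notumor = 2000,
                 pituitary = 1757)
  agg <- tapply(counts$images, counts$class, sum)
  classes <- sort(names(published))
  per_class <- data.frame(class = classes,
                          computed = as.integer(agg[classes]),
                          published = as.integer(published[classes]))
  per_class$match <- per_class$computed == per_class$published
  total <- sum(counts$images)
  list(per_class = per_class, total_computed = total,
       total_published = 7023, total_match = total == 7023)
}
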