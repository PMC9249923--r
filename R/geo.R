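#' Optionally fetch deposited count matrices from GEO
#'
#' Downloads and caches the supplementary files of one of the study-relevant
#' GEO series so real-data runs can replace the synthetic inputs. Strictly
#' opt-in and network-dependent: nothing in the package or its tests calls
#' this function.
#'
#' @param accession One of the supported GEO series accessions.
#' @param destdir Cache directory (default `tools::R_user_dir`-style local
#'   cache under `tempdir()`).
#' @return Character vector of local file paths.
#' @export
fetch_optional_geo <- function(accession,
                               destdir = file.path(tempdir(),
                                                   "planstate_geo")) {
  known <- c("GSE174246", "GSE174227", "GSE174228", "GSE107874",
             "GSE111764")
  if (!accession %in% known)
    stop("unsupported accession '", accession, "'; expected one of: ",
         paste(known, collapse = ", "))
  if (!dir.exists(destdir)) dir.create(destdir, recursive = TRUE)
  dest <- file.path(destdir, paste0(accession, "_suppl.tar"))
  if (file.exists(dest)) return(dest)
  url <- sprintf(
    "https://www.ncbi.nlm.nih.gov/geo/download/?acc=%s&format=file",
    accession)
  status <- tryCatch(utils::download.file(url, dest, mode = "wb",
                                          quiet = TRUE),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L)) {
    unlink(dest)
    stop("download of ", accession, " failed; network unavailable or ",
         "GEO unreachable. No files were written.")
  }
  dest
}
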