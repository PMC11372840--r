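#' Read a component property table
#'
#' Loads mixture components from a CSV with columns `name`, `M`, `v`,
#' `v_hc`, `eps`, `dispersion_class`, `Tm`, `dHfus`, `dCp_a`, `dCp_b`,
#' `sigma_file`, reading each component's sigma-profile from `sigma_file`
#' (relative paths resolve against `sigma_dir`). Missing optional columns
#' are treated as absent properties.
#'
#' @param path Path to the CSV table.
#' @param sigma_dir Directory against which relative `sigma_file` paths are
#'   resolved; defaults to the table's directory.
#' @return Named list of [component()]s.
#' @export
read_components <- function(path, sigma_dir = dirname(path)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "M", "sigma_file")
  if (!all(need %in% names(tab))) {
    stop("component table needs at least columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  opt <- function(col, default = NA_real_) {
    if (col %in% names(tab)) tab[[col]] else rep(default, nrow(tab))
  }
  v <- opt("v"); v_hc <- opt("v_hc"); eps <- opt("eps")
  dcl <- opt("dispersion_class", "nhb")
  Tm <- opt("Tm"); dh <- opt("dHfus")
  ca <- opt("dCp_a", 0); cb <- opt("dCp_b", 0)
  ca[is.na(ca)] <- 0; cb[is.na(cb)] <- 0
  dcl[is.na(dcl) | dcl == ""] <- "nhb"
  out <- lapply(seq_len(nrow(tab)), function(i) {
    sf <- tab$sigma_file[i]
    if (!file.exists(sf)) sf <- file.path(sigma_dir, sf)
    component(tab$name[i], read_sigma(sf), M = tab$M[i], v = v[i],
              v_hc = v_hc[i], eps = eps[i], dispersion_class = dcl[i],
              Tm = Tm[i], dHfus = dh[i], dCp_a = ca[i], dCp_b = cb[i])
  })
  names(out) <- tab$name
  out
}
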