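# MEME minimal motif format, the lingua franca for exchanging PWMs between
# motif tools. Only the fields the format requires are handled: the version
# line, an optional alphabet/background, and letter-probability matrices.

#' Read PWMs from a MEME minimal format file
#'
#' @param path file path.
#' @param pseudocount pseudocount attached to the returned [pwm()]s.
#' @return named list of [pwm()] objects.
#' @export
read_meme <- function(path, pseudocount = 0.1) {
  lines <- readLines(path)
  bkg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    if (length(vals) == 4 && !any(is.na(vals))) bkg <- vals / sum(vals)
  }
  starts <- grep("^MOTIF", lines)
  if (!length(starts)) stop("no MOTIF record in ", path)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- grep("^letter-probability matrix", lines[s:length(lines)])[1] + s - 1
    w <- as.integer(sub(".*w\\s*=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1):(h + w)]
    mat <- unname(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    mat <- sweep(mat, 2, colSums(mat), "/")   # 4 x W, rows A C G T
    out[[name]] <- pwm(mat, bkg, pseudocount, name = name)
  }
  out
}

#' Write a PWM in MEME minimal format
#'
#' @param p a [pwm()] or list of them.
#' @param path output path.
#' @export
write_meme <- function(p, path) {
  if (inherits(p, "pwm")) p <- setNames(list(p), p$name)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", c("A", "C", "G", "T"), p[[1]]$bkg),
                     collapse = " "), ""), con)
  for (nm in names(p)) {
    m <- p[[nm]]
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", m$width),
      con)
    for (j in seq_len(m$width))
      writeLines(paste(sprintf("%.6f", m$mat[, j]), collapse = "  "), con)
    writeLines("", con)
  }
  invisible(path)
}
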