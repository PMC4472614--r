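# Small fixtures shared across test files; everything is built in code.

# 5-edge toy graph: a-b, a-c, b-c, c-d, d-e
# degrees a:2 b:2 c:3 d:2 e:1, n_total = 5
toy_network <- function() {
  gene_network(rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                     c("c", "d"), c("d", "e")))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# tiny paired study: 3 lines x pre/post, deterministic values
tiny_study <- function(genes = 4, lines = 3, fun = function(g, s) g + s / 10) {
  ln <- paste0("L", seq_len(lines))
  samples <- data.frame(
    sample_id = c(paste0(ln, "_pre"), paste0(ln, "_post")),
    line_id = rep(ln, 2), condition = rep(c("pre", "post"), each = lines),
    inhibition = rep(ifelse(seq_len(lines) <= lines / 2, "high", "low"), 2),
    origin = "ex_vivo", stringsAsFactors = FALSE)
  x <- outer(seq_len(genes), seq_len(2 * lines), fun)
  rownames(x) <- paste0("g", seq_len(genes))
  colnames(x) <- samples$sample_id
  expression_study(x, samples)
}
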