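# Published 2x2 agreement tables between receptor/compartment marker calls
# (cells: pp = pos/pos, pn = pos/neg, np = neg/pos, nn = neg/neg) with the
# printed kappa and McNemar p as displayed.  `kappa_verifies` marks the
# pairs whose printed kappa recomputes from the printed cells to 3 dp; the
# two FALSE rows are known print discrepancies and are documented, not
# matched.
published_agreement <- function() {
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
pair           pp pn  np  nn  kappa  p_display kappa_verifies
her1m_her1c    13  4  77 104  0.115  <0.001    TRUE
her1m_her2m     5 12  29 152  0.092  0.008     TRUE
her1m_her3c    13  4 109  71  0.042  <0.001    TRUE
her1m_her4m     4 13  25 156  0.279  0.052     FALSE
her1m_her4c     5 12  44 137  0.028  <0.001    TRUE
her1c_her2m    17 73  17  91  0.033  <0.001    TRUE
her1c_her3c    58 31  64  44  0.057  <0.001    TRUE
her1c_her4m    10 80  19  89  0.000  <0.001    FALSE
her1c_her4c    27 63  22  86  0.100  <0.001    TRUE
her2m_her3c    23 11 101  65  0.033  <0.001    TRUE
her2m_her4m     7 27  22 143  0.077  0.475     TRUE
her2m_her4c    14 20  35 130  0.170  0.043     TRUE
her3c_her4m    24 99   5  70  0.103  <0.001    TRUE
her3c_her4c    35 88  14  61  0.082  <0.001    TRUE
her4m_her4c    13 16  36 134  0.184  0.006     TRUE
")
  tab
}

as_2x2 <- function(row) {
  matrix(c(row$pp, row$pn, row$np, row$nn), nrow = 2, byrow = TRUE,
         dimnames = list(c("pos", "neg"), c("pos", "neg")))
}

# Published marker positives and stage-group denominators with the printed
# chi-square p; `p_verifies` marks rows that recompute under plain Pearson.
published_positivity <- function() {
  list(
    her1_membrane  = list(pos = c(6, 9, 1),    n = c(72, 93, 30),
                          p = 0.545, p_verifies = TRUE),
    her1_cytoplasm = list(pos = c(31, 44, 14), n = c(72, 93, 30),
                          p = 0.258, p_verifies = FALSE),
    her2_membrane  = list(pos = c(14, 15, 5),  n = c(75, 93, 30),
                          p = 0.907, p_verifies = TRUE),
    her3_cytoplasm = list(pos = c(43, 56, 23), n = c(75, 92, 30),
                          p = 0.176, p_verifies = TRUE),
    her4_membrane  = list(pos = c(12, 11, 4),  n = c(73, 93, 30),
                          p = 0.692, p_verifies = TRUE),
    her4_cytoplasm = list(pos = c(20, 24, 5),  n = c(73, 93, 30),
                          p = 0.321, p_verifies = FALSE))
}

positivity_matrix <- function(x) {
  rbind(pos = x$pos, neg = x$n - x$pos)
}

# small hand cohort used across I/O tests
tiny_cohort_df <- function() {
  data.frame(
    id = c("a", "b", "c"), time_months = c(1, 2, 3), event = c(1L, 0L, 1L),
    postop_death = c(0L, 0L, 0L), age = c(60L, 70L, 55L),
    lauren = c("intestinal", "diffuse", NA),
    stage = c("IA", "IIIB", "IVM1"),
    her2_membrane = c(3L, 0L, NA), stringsAsFactors = FALSE)
}
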