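# Shared fixtures and independent oracles, all built in code.

# Compact panel builder: `rows` is a list of c(id, item, imp, chg) entries
# (scores may be NA), on the default two-criterion roster.
make_panel <- function(rows, k = 3,
                       criteria = c("importance", "changeability"),
                       strata = NULL) {
  recs <- do.call(rbind, lapply(rows, function(r) {
    data.frame(stakeholder_id = as.character(r[[1]]),
               item_id = as.character(r[[2]]),
               criterion = criteria,
               score = as.numeric(r[3:(2 + length(criteria))]),
               stringsAsFactors = FALSE)
  }))
  rating_panel(recs, k = k, criteria = criteria, strata = strata)
}

# One item, one row per stakeholder: scores is a 2-column matrix (or a list
# of length-2 vectors) of importance/changeability scores.
one_item_panel <- function(scores, item = "q1", k = 3) {
  if (is.list(scores)) scores <- do.call(rbind, scores)
  rows <- lapply(seq_len(nrow(scores)), function(i) {
    c(paste0("s", i), item, scores[i, 1], scores[i, 2])
  })
  make_panel(rows, k = k)
}

# Independent brute-force oracle for the CPI of one item: plain loops over
# records, nothing shared with the package's aggregation path.
brute_force_cpi <- function(panel, item_id) {
  cpi <- 1
  for (crit in panel$criteria) {
    total <- 0
    count <- 0
    r <- panel$records
    for (i in seq_len(nrow(r))) {
      if (r$item_id[i] == item_id && r$criterion[i] == crit &&
          !is.na(r$score[i])) {
        total <- total + r$score[i]
        count <- count + 1
      }
    }
    if (count == 0) return(NA_real_)
    cpi <- cpi * total / count
  }
  cpi
}

# Published worked example of CPI scoring: three subpopulations with
# unbalanced issue lists, observed CPIs with bootstrap 95% CIs on the raw
# [1, 9] scale (k = 3, two criteria) and their printed standardized forms.
reference_priority_table <- function() {
  txt <- "population,issue,observed,lo,hi,std,std_lo,std_hi
A,A1,7.80,6.60,9.00,0.85,0.70,1.00
A,A2,7.93,6.50,9.00,0.87,0.69,1.00
A,A3,6.93,5.50,8.50,0.74,0.56,0.94
A,A4,6.67,5.42,8.03,0.71,0.55,0.88
A,A5,7.00,6.00,8.00,0.75,0.63,0.88
A,A6,6.05,4.95,7.20,0.63,0.49,0.78
A,A7,5.67,4.25,7.08,0.58,0.41,0.76
A,A8,5.50,4.50,6.00,0.56,0.44,0.63
A,A9,3.24,1.80,5.28,0.28,0.10,0.54
B,B1,7.93,6.50,9.00,0.87,0.69,1.00
B,B2,7.37,5.87,8.50,0.80,0.61,0.94
B,B3,6.61,5.42,8.00,0.70,0.55,0.88
B,B4,6.00,4.50,7.50,0.63,0.44,0.81
B,B5,5.83,4.67,7.11,0.60,0.46,0.76
B,B6,5.50,4.00,7.00,0.56,0.38,0.75
B,B7,4.80,3.36,6.24,0.48,0.30,0.66
C,C1,8.03,6.67,9.00,0.88,0.69,1.00
C,C2,7.50,6.50,8.50,0.81,0.69,0.94
C,C3,7.00,5.00,8.50,0.75,0.50,0.94
C,C4,6.61,5.33,8.00,0.70,0.54,0.88
C,C5,5.67,4.25,7.08,0.58,0.41,0.76"
  utils::read.csv(text = txt, stringsAsFactors = FALSE)
}

# Small random panel (<= 4 stakeholders, <= 3 items) with some abstentions,
# for brute-force oracle comparisons.
with_seed_panel <- function(seed, k = 3) {
  set.seed(seed)
  n_s <- sample(2:4, 1)
  n_q <- sample(1:3, 1)
  rows <- list()
  for (i in seq_len(n_s)) {
    for (q in seq_len(n_q)) {
      sc <- sample(c(NA, seq_len(k)), 2, replace = TRUE,
                   prob = c(0.2, rep(0.8 / k, k)))
      rows[[length(rows) + 1]] <- c(paste0("s", i), paste0("q", q),
                                    sc[1], sc[2])
    }
  }
  make_panel(rows, k = k)
}

write_csv_fixture <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

sorted_records <- function(panel) {
  r <- panel$records
  r <- r[order(r$stakeholder_id, r$item_id, r$criterion), ]
  rownames(r) <- NULL
  r
}
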