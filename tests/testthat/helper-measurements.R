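# the published per-plasma calibration summaries for the two WHO
# thromboplastin IRPs, built in code so tests are self-contained
example_rows <- function() {
  tibble::tribble(
    ~irp_id,      ~plasma_id, ~pt_mean_s, ~sd_log_pt, ~n, ~mnpt_s, ~sd_log_mnpt, ~m, ~isi, ~sd_isi,
    "rTF/16",     "Lyo A",    12.17,      0.021,      10, 12.17,   0.014,        6,  1.11, 0.063,
    "rTF/16",     "Lyo B",    25.25,      0.0090,     10, 12.17,   0.014,        6,  1.11, 0.063,
    "rTF/16",     "Lyo C",    36.64,      0.011,      10, 12.17,   0.014,        6,  1.11, 0.063,
    "rTF/16",     "Lyo D",    56.46,      0.020,      10, 12.17,   0.014,        6,  1.11, 0.063,
    "IRP 24/114", "Lyo A",    10.69,      0.016,      10, 11.28,   0.016,        2,  1.08, 0.030,
    "IRP 24/114", "Lyo B",    19.80,      0.016,      10, 11.28,   0.016,        2,  1.08, 0.030,
    "IRP 24/114", "Lyo C",    29.38,      0.016,      10, 11.28,   0.016,        2,  1.08, 0.030,
    "IRP 24/114", "Lyo D",    41.70,      0.017,      10, 11.28,   0.016,        2,  1.08, 0.030
  )
}

# the published outputs of the same table (display-rounded as printed)
printed_outputs <- function() {
  tibble::tribble(
    ~irp_id,      ~plasma_id, ~mean_inr, ~sd_log_inr, ~ci_lower, ~ci_upper, ~ru_percent,
    "rTF/16",     "Lyo A",    1.00,      0.010,       0.98,      1.02,      1.0,
    "rTF/16",     "Lyo B",    2.25,      0.047,       2.05,      2.47,      4.7,
    "rTF/16",     "Lyo C",    3.40,      0.070,       2.95,      3.91,      7.0,
    "rTF/16",     "Lyo D",    5.49,      0.098,       4.52,      6.67,      9.8,
    "IRP 24/114", "Lyo A",    0.94,      0.014,       0.92,      0.97,      1.4,
    "IRP 24/114", "Lyo B",    1.84,      0.022,       1.76,      1.92,      2.2,
    "IRP 24/114", "Lyo C",    2.81,      0.032,       2.64,      3.00,      3.2,
    "IRP 24/114", "Lyo D",    4.10,      0.042,       3.78,      4.46,      4.2
  )
}

example_row <- function(irp, plasma) {
  tab <- example_rows()
  tab[tab$irp_id == irp & tab$plasma_id == plasma, ]
}

# independent oracle for the propagation: the literal three-addend formula,
# spelled out term by term (kept separate from the package implementation)
oracle_sd_log_inr <- function(row) {
  ln_r <- log(row$pt_mean_s / row$mnpt_s)
  sqrt((row$isi * row$sd_log_pt)^2 / row$n +
         (row$isi * row$sd_log_mnpt)^2 / row$m +
         (ln_r * row$sd_isi)^2)
}
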