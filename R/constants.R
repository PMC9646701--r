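# Scoring constants of the conditioned-response definition. These are the
# defaults of the corresponding function arguments; the simulator uses the
# same values so that every conditioned response it plants is detectable by
# a scorer run at defaults.

CR_AMP_THRESHOLD_NEC <- 0.1    # minimum CR peak amplitude, NEC
CR_ONSET_WINDOW_MS <- c(50, 500)   # admissible CR onset latency (closed)
CR_PEAK_WINDOW_MS <- c(100, 1000)  # admissible CR peak latency (closed)
CR_ONSET_THRESHOLD_NEC <- 0.02 # sustained-crossing threshold defining onset
CR_SUSTAIN_MS <- 10            # minimum time above threshold at onset
PERFECT_HALF_WINDOW_MS <- 50   # half-width of the perfectly-timed window
VALIDITY_IQR_K <- 7            # pre-CS excursion limit, multiples of IQR
FILTER_CUTOFF_HZ <- 50         # low-pass cutoff
FILTER_ORDER <- 4              # Butterworth order (applied forward-backward)
ROTAROD_CENSOR_S <- 300        # latency-to-fall censoring bound
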