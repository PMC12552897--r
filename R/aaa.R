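## Shared constants (loaded first).

## the four sensor-estimated sleep states
STATE_LEVELS <- c("AWAKE", "LIGHT", "DEEP", "REM")

## canonical metric column order of a night record
NIGHT_METRIC_COLS <- c("TO_BED", "ARISE", "NOP", "IBT", "IBP", "OBT",
                       "EXITS", "EXIT_DUR", "DEEP_DUR", "AWAKE_DUR",
                       "REM_DUR", "LIGHT_DUR", "SNT", "WSA_DEEP",
                       "WSA_AWAKE", "WSA_REM", "WSA_LIGHT", "HR", "RR", "SNR")

## feature set used by the phenotype state classifier
STATE_FEATURES <- c("IBT", "TO_BED", "ARISE", "NOP", "OBT", "EXITS",
                    "EXIT_DUR")

## feature set of the sleep-disturbance index: the full nightly metric vector
DRI_FEATURES <- NIGHT_METRIC_COLS
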