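# Shared vocabulary: the four upper-limb markers (distal to proximal),
# coordinate axes, limb classes and protocol activities.

MARKERS <- c("FN", "LEP", "MPH", "ACR")
AXES <- c("x", "y", "z")
CLASS_LABELS <- c("G0", "G1", "G2")
SIDES <- c("left", "right")
ACTIVITIES <- c("large_cylinder", "small_cylinder", "drinking")
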