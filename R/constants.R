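# Fixed channel layout of the two-insole sensor suite.

N_PRESSURE <- 16L        # 8 pressure sensors per foot, left 1-8 then right 9-16
N_ACCEL <- 6L            # left x,y,z then right x,y,z
N_GYRO <- 6L
LEFT_PRESSURE <- 1:8     # left-foot pressure channels within the 16-column array
N_COLUMNS <- N_PRESSURE + N_ACCEL + N_GYRO
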