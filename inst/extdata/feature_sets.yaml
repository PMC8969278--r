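# Default feature-set definitions for read_feature_sets(). The standard
# set carries the classic spatiotemporal parameters; the augmented set
# replaces the signed toe angle with magnitude + direction and adds the
# foot-geometry features.
standard:
  numeric_features:
    - step_time
    - stride_time
    - step_velocity
    - stride_velocity
    - single_support_time
    - double_support_time
    - stance_time
    - step_length
    - step_width
    - stride_length
    - stride_width
    - base_width
    - toe_angle_signed
  categorical_features:
    - foot_type
augmented:
  numeric_features:
    - step_time
    - stride_time
    - step_velocity
    - stride_velocity
    - single_support_time
    - double_support_time
    - stance_time
    - step_length
    - step_width
    - stride_length
    - stride_width
    - base_width
    - toe_angle_unsigned
    - foot_length
    - foot_width
    - foot_area
    - hull_area
    - bos_area
    - lop_deviation_angle
  categorical_features:
    - foot_type
    - toe_direction
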