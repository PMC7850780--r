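# Synthetic default message bank: mirrors the 10-message structure used in
# the survey (8 false, 2 true); the false messages are split 4/4 between
# those carrying background evidence (attached link and/or named source)
# and those without. Message texts are not reproduced; ids are synthetic.
messages:
  - { message_id: m01, truth_label: "false", evidence_flag: has_link_or_source }
  - { message_id: m02, truth_label: "false", evidence_flag: has_link_or_source }
  - { message_id: m03, truth_label: "false", evidence_flag: has_link_or_source }
  - { message_id: m04, truth_label: "false", evidence_flag: has_link_or_source }
  - { message_id: m05, truth_label: "false", evidence_flag: none }
  - { message_id: m06, truth_label: "false", evidence_flag: none }
  - { message_id: m07, truth_label: "false", evidence_flag: none }
  - { message_id: m08, truth_label: "false", evidence_flag: none }
  - { message_id: m09, truth_label: "true", evidence_flag: has_link_or_source }
  - { message_id: m10, truth_label: "true", evidence_flag: none }
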