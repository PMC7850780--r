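# Default scoring rubric: 9 question groups, 13 individually scored items,
# s_max = 46. P8 is derived from the count of incorrect message judgments.
groups:
  P1:
    label: "Duration of WhatsApp use per day"
    items: [duration]
    options:
      "0-30 minutes": 1
      "30 minutes to 1 hour": 2
      "1-2 hours": 3
      ">2 hours": 4
  P2:
    label: "Priority of WhatsApp for communication"
    items: [communication]
    options:
      "Low": 1
      "Moderate": 2
      "High": 3
  P3:
    label: "Priority of WhatsApp for news and information"
    items: [information]
    options:
      "Low": 1
      "Moderate": 2
      "High": 3
  P4:
    label: "Source for COVID-19-related updates"
    items: [covid_source]
    options:
      "Neither social media nor WhatsApp": 0
      "Social media but no WhatsApp": 2
      "WhatsApp": 4
  P5:
    label: "Trust placed in COVID-19-related WhatsApp messages"
    items: [trust]
    options:
      "0%": 0
      "25%": 1
      "50%": 2
      "75%": 3
      "100%": 4
  P6:
    label: "COVID-19 message forwards per day"
    items: [forwards]
    options:
      "0-2": 1
      "3-5": 2
      "6-8": 3
      "More than 8": 4
  P7:
    label: "Fact-check rate before forwarding"
    items: [fact_check]
    options:
      "75-100%": 1
      "50-75%": 2
      "25-50%": 3
      "0-25%": 4
      "Never": 5
  P8:
    label: "Incorrect message judgments"
    derived_from: incorrect_count
    bins:
      - { label: "0-2", max: 2, score: 1 }
      - { label: "3-5", max: 5, score: 2 }
      - { label: "6-8", max: 8, score: 3 }
      - { label: "More than 8", max: .inf, score: 4 }
  P9:
    label: "Actions taken on unverified remedy messages"
    items: [allopathic, herbal, ayurvedic, homeopathic, home]
    options:
      "Never considered using": 0
      "Considered but not used": 1
      "Used once": 2
      "Using regularly and recommending": 3
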