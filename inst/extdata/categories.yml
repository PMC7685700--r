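adult:
  keywords: ["porn*", "xxx", "nsfw", "explicit"]
  domains: ["pornhub.com", "xvideos.com", "onlyfans.com"]
news:
  keywords: ["news", "headline*", "election*", "pandemic", "outbreak", "lockdown"]
  domains: ["cnn.com", "nytimes.com", "bbc.com", "reuters.com", "foxnews.com"]
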