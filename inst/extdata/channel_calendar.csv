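channel,start,end
facebook_ad,2022-01-26,2022-07-25
community_flyer,2022-01-26,2022-07-25
listserv,2022-01-26,2022-07-25
postcard,2022-01-26,2022-07-25
radio_ad,,
tv_ad,,
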