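post_id,subject_id,timestamp,text
e1,s1,2015-10-05T12:00,"lunch on campus was great today"
e2,s1,2015-10-05T22:00,"still studying in the library, long night ahead"
e3,s1,2015-10-05T23:00,"so tired, this essay is never ending"
e4,s1,2015-10-06T13:45,"zzz"
e5,s1,2015-10-06T16:00,"that nap did not help, exhausted"
e6,s1,2015-10-06T22:30,"cannot focus anymore, brain is done"
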