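>A*02:01 synthetic stand-in; cleft positions 57-73 and 163 as documented
MAVMAPRTLLLLLSGALALTQTWAGSHSMRYFETSAVQWLRKDAGSHSMRYFETSAVQWLRKDAGSHSMRYFETSAVQWLPEYWDGETRKVKAHSQTQWLRKDAGSHSMRYFETSAVQWLRKDAGSHSMRYFETSAVQWLRKDAGSHSMRYFETSAVQWLRKDAGSHSMRYFETSAVQWLRKDAGSTSMRYFETSAVQWLRKDAGSHSMRYFETSAVQWLRKDA
>A*24:02 synthetic stand-in; cleft positions 57-73 and 163 as documented
MAVMAPRTLLLLLSGALALTQTWAGSHSMRYFETSAVQWLRKDAGSHSMRYFETSAVQWLRKDAGSHSMRYFETSAVQWLPEYWDEETGKVKAHSQTQWLRKDAGSHSMRYFETSAVQWLRKDAGSHSMRYFETSAVQWLRKDAGSHSMRYFETSAVQWLRKDAGSHSMRYFETSAVQWLRKDAGSESMRYFETSAVQWLRKDAGSHSMRYFETSAVQWLRKDA
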